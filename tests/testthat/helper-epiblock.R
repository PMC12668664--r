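# Shared fixtures and independent oracles for the test suite.  Oracles
# here are deliberately naive (grids, enumeration, Monte-Carlo) and
# never call the implementation paths they check.

make_atoms <- function(n, chain = "X", resno = seq_len(n), atom = "CA",
                       element = "C", resid = "ALA",
                       x = 0, y = 0, z = 0) {
  data.frame(chain = chain, resno = resno, ins = "", resid = resid,
             atom = atom, element = element, x = x, y = y, z = z,
             occ = 1, b = 0, altloc = "", het = FALSE,
             stringsAsFactors = FALSE)
}

random_atoms <- function(n, box = 30, chain = "X") {
  make_atoms(n, chain = chain,
             x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box))
}

coords_of <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

shift_atoms <- function(atoms, tr) {
  atoms[, c("x", "y", "z")] <- apply_transform(tr, coords_of(atoms))
  atoms
}

# Multi-chain helix bundle with designed chain lengths, spaced apart.
helix_bundle <- function(lengths, chains = LETTERS[seq_along(lengths)],
                         spacing = 60, backbone = FALSE) {
  parts <- lapply(seq_along(lengths), function(i) {
    a <- build_ideal_helix(lengths[i], chain_id = chains[i],
                           backbone = backbone)$atoms
    a$x <- a$x + spacing * i
    a
  })
  structure_model(do.call(rbind, parts), id = "bundle")
}

# ---- brute-force rotation-grid oracle for Kabsch ---------------------------

euler_rotation <- function(a, b, g) {
  Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz2 <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz1 %*% Ry %*% Rz2
}

# Minimal RMSD by exhaustive search over proper rotations (5-degree
# Euler grid, then local refinement), independent of any SVD.
brute_rotation_rmsd <- function(ref, mov, step_deg = 5) {
  rc <- sweep(ref, 2, colMeans(ref)); mc <- sweep(mov, 2, colMeans(mov))
  Ht <- t(crossprod(mc, rc))
  score <- function(p) sum(euler_rotation(p[1], p[2], p[3]) * Ht)
  st <- step_deg * pi / 180
  grid <- expand.grid(a = seq(0, 2 * pi - st, by = st),
                      b = seq(0, pi, by = st),
                      g = seq(0, 2 * pi - st, by = st))
  sc <- apply(grid, 1, score)
  op <- optim(as.numeric(grid[which.max(sc), ]), function(p) -score(p))
  sqrt(max(0, sum(rc^2) + sum(mc^2) + 2 * op$value) / nrow(ref))
}

# ---- tiny Needleman-Wunsch oracle (affine gaps: open+L*extend) -------------

nw_align_pairs <- function(sa, sb, match = 1, mismatch = -1,
                           open = 2, extend = 1) {
  n <- length(sa); m <- length(sb)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -open - i * extend
  for (j in seq_len(m)) Iy[1, j + 1] <- -open - j * extend
  ptr <- array("", c(n + 1, m + 1, 3))
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (sa[i] == sb[j]) match else mismatch
    cand <- c(M[i, j], Ix[i, j], Iy[i, j])
    M[i + 1, j + 1] <- max(cand) + s
    ptr[i + 1, j + 1, 1] <- c("M", "Ix", "Iy")[which.max(cand)]
    cx <- c(M[i, j + 1] - open - extend, Ix[i, j + 1] - extend)
    Ix[i + 1, j + 1] <- max(cx)
    ptr[i + 1, j + 1, 2] <- c("M", "Ix")[which.max(cx)]
    cy <- c(M[i + 1, j] - open - extend, Iy[i + 1, j] - extend)
    Iy[i + 1, j + 1] <- max(cy)
    ptr[i + 1, j + 1, 3] <- c("M", "Iy")[which.max(cy)]
  }
  state <- c("M", "Ix", "Iy")[which.max(c(M[n + 1, m + 1],
                                          Ix[n + 1, m + 1],
                                          Iy[n + 1, m + 1]))]
  i <- n; j <- m; pairs <- NULL
  while (i > 0 || j > 0) {
    if (state == "M" && i > 0 && j > 0) {
      pairs <- rbind(c(i, j), pairs)
      state <- ptr[i + 1, j + 1, 1]; i <- i - 1; j <- j - 1
    } else if (state == "Ix" && i > 0) {
      state <- ptr[i + 1, j + 1, 2]; i <- i - 1
    } else if (state == "Iy" && j > 0) {
      state <- ptr[i + 1, j + 1, 3]; j <- j - 1
    } else if (i > 0) { state <- "Ix" } else state <- "Iy"
  }
  pairs
}

# ---- Monte-Carlo two-sphere accessible-area oracle -------------------------

mc_two_sphere <- function(r1, r2, d, probe, n = 1e5) {
  R1 <- r1 + probe; R2 <- r2 + probe
  pt <- matrix(rnorm(3 * n), n, 3)
  pt <- pt / sqrt(rowSums(pt^2))
  p1 <- pt * R1                       # sphere 1 at origin, sphere 2 at (d,0,0)
  a1 <- mean((p1[, 1] - d)^2 + p1[, 2]^2 + p1[, 3]^2 > R2^2) * 4 * pi * R1^2
  p2 <- sweep(pt * R2, 2, c(d, 0, 0), "+")
  a2 <- mean(rowSums(p2^2) > R1^2) * 4 * pi * R2^2
  c(a1, a2)
}

# Brute-force closest-contact-per-residue-pair reduction.
brute_reduce <- function(tab) {
  key <- paste(tab$chain_a, tab$resno_a, tab$ins_a,
               tab$chain_b, tab$resno_b, tab$ins_b, sep = "|")
  do.call(rbind, lapply(split(tab, key), function(g) {
    g[order(g$distance, g$atom_a, g$atom_b), ][1, ]
  }))
}

expect_same_contacts <- function(a, b, tol = 1e-9) {
  key <- function(t) paste(t$chain_a, t$resno_a, t$atom_a,
                           t$chain_b, t$resno_b, t$atom_b)
  expect_equal(nrow(a), nrow(b))
  expect_setequal(key(a), key(b))
  m <- match(key(a), key(b))
  expect_equal(a$distance, b$distance[m], tolerance = tol)
}
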