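# Independent brute-force oracles for the texture-matrix families. These
# deliberately use naive explicit loops (no shifts, no igraph, no tabulate
# tricks) so they share no code path with the package implementation.

# build a quantized-lesion-like object from an integer array (NA = outside)
q_fixture <- function(arr, n_levels = max(arr, na.rm = TRUE)) {
  if (length(dim(arr)) < 3) dim(arr) <- c(dim(arr), rep(1L, 3 - length(dim(arr))))
  structure(list(levels = array(as.integer(arr), dim(arr)),
                 n_levels = as.integer(n_levels),
                 mask = !is.na(arr), spacing = c(1, 1, 1),
                 min_suv = 0, max_suv = 1),
            class = "quantized_lesion")
}

all_dirs_26 <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
}

in_bounds <- function(p, dm) all(p >= 1) && all(p <= dm)

# symmetric co-occurrence counts by enumerating every ordered voxel pair
oracle_glcm <- function(q, dirs = NULL) {
  lv <- q$levels
  dm <- dim(lv)
  dd <- if (is.null(dirs)) all_dirs_26() else rbind(dirs, -dirs)
  C <- matrix(0, q$n_levels, q$n_levels)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    for (r in seq_len(nrow(dd))) {
      p <- c(i, j, k) + dd[r, ]
      if (!in_bounds(p, dm)) next
      b <- lv[p[1], p[2], p[3]]
      if (!is.na(b)) C[a, b] <- C[a, b] + 1
    }
  }
  C
}

# maximal collinear same-level runs by explicit walking, one direction
oracle_runs_dir <- function(q, d) {
  lv <- q$levels
  dm <- dim(lv)
  runs <- list()
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    prev <- c(i, j, k) - d
    prev_same <- in_bounds(prev, dm) &&
      !is.na(lv[prev[1], prev[2], prev[3]]) &&
      lv[prev[1], prev[2], prev[3]] == a
    if (prev_same) next
    len <- 1
    p <- c(i, j, k) + d
    while (in_bounds(p, dm) && !is.na(lv[p[1], p[2], p[3]]) &&
           lv[p[1], p[2], p[3]] == a) {
      len <- len + 1
      p <- p + d
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  do.call(rbind, runs)
}

oracle_run_features <- function(q, dirs) {
  runs <- do.call(rbind, lapply(seq_len(nrow(dirs)),
                                function(r) oracle_runs_dir(q, dirs[r, ])))
  lev <- runs[, 1]; len <- runs[, 2]
  nr <- nrow(runs)
  np <- sum(!is.na(q$levels)) * nrow(dirs)
  c(sum(1 / len^2) / nr, sum(len^2) / nr,
    sum(tapply(rep(1, nr), lev, sum)^2) / nr,
    sum(tapply(rep(1, nr), len, sum)^2) / nr,
    nr / np,
    sum(1 / lev^2) / nr, sum(lev^2) / nr,
    sum(1 / (lev^2 * len^2)) / nr, sum(lev^2 / len^2) / nr,
    sum(len^2 / lev^2) / nr, sum(lev^2 * len^2) / nr)
}

# 26-connected same-level zones by stack-based flood fill
oracle_zones <- function(q) {
  lv <- q$levels
  dm <- dim(lv)
  seen <- array(FALSE, dm)
  dd <- all_dirs_26()
  zones <- list()
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (seen[i, j, k] || is.na(lv[i, j, k])) next
    a <- lv[i, j, k]
    stack <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(dd))) {
        np_ <- p + dd[r, ]
        if (in_bounds(np_, dm) && !seen[np_[1], np_[2], np_[3]] &&
            !is.na(lv[np_[1], np_[2], np_[3]]) &&
            lv[np_[1], np_[2], np_[3]] == a) {
          seen[np_[1], np_[2], np_[3]] <- TRUE
          stack[[length(stack) + 1]] <- np_
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  do.call(rbind, zones)
}

oracle_zone_features <- function(q) {
  z <- oracle_zones(q)
  lev <- z[, 1]; size <- z[, 2]
  nz <- nrow(z)
  np <- sum(!is.na(q$levels))
  c(sum(1 / size^2) / nz, sum(size^2) / nz,
    sum(tapply(rep(1, nz), lev, sum)^2) / nz,
    sum(tapply(rep(1, nz), size, sum)^2) / nz,
    nz / np,
    sum(1 / lev^2) / nz, sum(lev^2) / nz,
    sum(1 / (lev^2 * size^2)) / nz, sum(lev^2 / size^2) / nz,
    sum(size^2 / lev^2) / nz, sum(lev^2 * size^2) / nz)
}

# Amadasun-King quantities by direct summation
oracle_ngtdm <- function(q) {
  lv <- q$levels
  dm <- dim(lv)
  dd <- all_dirs_26()
  L <- q$n_levels
  s <- rep(0, L); n <- rep(0, L)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    vals <- c()
    for (r in seq_len(nrow(dd))) {
      p <- c(i, j, k) + dd[r, ]
      if (in_bounds(p, dm) && !is.na(lv[p[1], p[2], p[3]])) {
        vals <- c(vals, lv[p[1], p[2], p[3]])
      }
    }
    if (length(vals) == 0) next
    s[a] <- s[a] + abs(a - mean(vals))
    n[a] <- n[a] + 1
  }
  list(s = s, n = n, N = sum(n))
}

oracle_nid_features <- function(q) {
  tb <- oracle_ngtdm(q)
  p <- tb$n / tb$N
  pres <- which(p > 0)
  Ng <- length(pres)
  coarse <- min(1 / (1e-6 + sum(p * tb$s)), 1e6)
  if (Ng < 2) return(c(coarse, 0, 0, 0, 0))
  contr <- 0; den_b <- 0; compl <- 0; strength <- 0
  for (i in pres) for (j in pres) {
    contr <- contr + p[i] * p[j] * (i - j)^2
    den_b <- den_b + abs(i * p[i] - j * p[j])
    compl <- compl + abs(i - j) * (p[i] * tb$s[i] + p[j] * tb$s[j]) /
      (tb$N * (p[i] + p[j]))
    strength <- strength + (p[i] + p[j]) * (i - j)^2
  }
  c(coarse,
    contr / (Ng * (Ng - 1)) * sum(tb$s) / tb$N,
    if (den_b > 0) sum(p * tb$s) / den_b else 0,
    compl,
    strength / (1e-6 + sum(tb$s)))
}

# dependence counts by explicit neighbour loops
oracle_ngld_features <- function(q) {
  lv <- q$levels
  dm <- dim(lv)
  dd <- all_dirs_26()
  recs <- list()
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    dep <- 0
    for (r in seq_len(nrow(dd))) {
      p <- c(i, j, k) + dd[r, ]
      if (in_bounds(p, dm) && !is.na(lv[p[1], p[2], p[3]]) &&
          lv[p[1], p[2], p[3]] == a) dep <- dep + 1
    }
    recs[[length(recs) + 1]] <- c(a, dep)
  }
  m <- do.call(rbind, recs)
  N <- nrow(m)
  key <- paste(m[, 1], m[, 2])
  Q <- table(key)
  sv <- as.numeric(sub(".* ", "", names(Q)))
  Qn <- as.numeric(Q)
  c(sum(Qn / (sv + 1)^2) / N, sum(Qn * (sv + 1)^2) / N,
    sum(tapply(Qn, sv, sum)^2) / N, sum(Qn^2) / N^2,
    -sum((Qn / N) * log2(Qn / N)))
}

# gradient-class coded map by explicit loops (mirrors the documented coding)
oracle_tfc_map <- function(q) {
  lv <- q$levels
  dm <- dim(lv)
  dd <- all_dirs_26()
  dd <- dd[apply(dd, 1, function(d) d[which(d != 0)[1]] > 0), , drop = FALSE]
  code <- array(NA_integer_, dm)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    tot <- 0; nv <- 0
    for (r in seq_len(nrow(dd))) {
      pm <- c(i, j, k) - dd[r, ]; pp <- c(i, j, k) + dd[r, ]
      if (!in_bounds(pm, dm) || !in_bounds(pp, dm)) next
      b <- lv[pm[1], pm[2], pm[3]]; cc <- lv[pp[1], pp[2], pp[3]]
      if (is.na(b) || is.na(cc)) next
      d1 <- a - b; d2 <- cc - a
      cls <- if (d1 == 0 && d2 == 0) 0 else if (d1 * d2 >= 0) 1 else 2
      tot <- tot + cls; nv <- nv + 1
    }
    if (nv > 0) code[i, j, k] <- tot
  }
  code
}

haralick_oracle <- function(P) {
  # direct double loop over matrix cells
  L <- nrow(P)
  sam <- 0; contrast <- 0; ent <- 0; hom <- 0; dis <- 0; idm <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    if (p == 0) next
    sam <- sam + p^2
    contrast <- contrast + (i - j)^2 * p
    ent <- ent - p * log2(p)
    hom <- hom + p / (1 + abs(i - j))
    dis <- dis + abs(i - j) * p
    idm <- idm + p / (1 + (i - j)^2)
  }
  mi <- sum((1:L) * rowSums(P)); mj <- sum((1:L) * colSums(P))
  si <- sqrt(sum(outer((1:L - mi)^2, rep(1, L)) * P))
  sj <- sqrt(sum(outer(rep(1, L), (1:L - mj)^2) * P))
  corr <- if (si > 0 && sj > 0) {
    sum(outer(1:L - mi, 1:L - mj) * P) / (si * sj)
  } else 0
  c(sam = sam, contrast = contrast, entropy = ent, homogeneity = hom,
    dissimilarity = dis, idm = idm, correlation = corr)
}

# deterministic random lesion fixture: arbitrary levels in a box with a
# few NA (out-of-mask) voxels
random_q <- function(dim3, n_levels = 4, seed = 42, na_frac = 0.15) {
  set.seed(seed)
  arr <- array(sample.int(n_levels, prod(dim3), replace = TRUE), dim3)
  arr[sample.int(prod(dim3), round(na_frac * prod(dim3)))] <- NA
  if (all(is.na(arr))) arr[1] <- 1L
  q_fixture(arr, n_levels)
}
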