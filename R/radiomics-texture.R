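# The 59 texture features from 9 parent matrix families, computed on the
# 64-level quantized 3D grid with 26-voxel connectivity. Matrices are
# accumulated (summed) over the 13 unique direction offsets before
# normalization; entropy-type features use log2.

texture_eps <- 1e-6

# ---- grey-level co-occurrence -------------------------------------------

#' Symmetric grey-level co-occurrence counts at distance 1
#'
#' Counts ordered in-mask voxel pairs over the given direction offsets and
#' symmetrizes, so pair (i,j) and (j,i) both contribute.
#' @param q a `quantized_lesion`
#' @param directions integer matrix of offsets (default all 13 unique
#'   26-connectivity directions)
#' @return L x L count matrix
#' @keywords internal
glcm_counts <- function(q, directions = offsets13()) {
  L <- q$n_levels
  lv <- q$levels
  C <- matrix(0, L, L)
  for (r in seq_len(nrow(directions))) {
    nb <- shift3d(lv, -directions[r, ])          # nb[x] = lv[x + d]
    ok <- !is.na(lv) & !is.na(nb)
    if (!any(ok)) next
    cell <- (lv[ok] - 1L) * L + nb[ok]
    C <- C + matrix(tabulate(cell, nbins = L * L), L, L, byrow = TRUE)
  }
  C + t(C)
}

haralick_features <- function(P, with_correlation = TRUE) {
  idx <- which(P > 0, arr.ind = TRUE)
  p <- P[idx]
  i <- idx[, 1]; j <- idx[, 2]
  sam <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  entropy <- -sum(p * log2(p))
  homog <- sum(p / (1 + abs(i - j)))
  dissim <- sum(abs(i - j) * p)
  idm <- sum(p / (1 + (i - j)^2))
  out <- c(second_angular_moment = sam, contrast = contrast, entropy = entropy,
           homogeneity = homog, dissimilarity = dissim,
           inverse_difference_moment = idm)
  if (with_correlation) {
    mu_i <- sum(i * p); mu_j <- sum(j * p)
    s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
    corr <- if (s_i > 0 && s_j > 0) sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j) else 0
    out <- c(out, correlation = corr)
  }
  out
}

#' Co-occurrence matrix features (7)
#'
#' Second angular moment, contrast, entropy, homogeneity, dissimilarity,
#' inverse difference moment, correlation, on the probability-normalized
#' symmetric GLCM. Correlation of a constant lesion is defined as 0.
#' @param q a `quantized_lesion`
#' @param directions offset matrix, default the 13 unique directions
#' @export
cooccurrence_features <- function(q, directions = offsets13()) {
  C <- glcm_counts(q, directions)
  nm <- c("second_angular_moment", "contrast", "entropy", "homogeneity",
          "dissimilarity", "inverse_difference_moment", "correlation")
  if (sum(C) == 0) {
    return(stats::setNames(rep(NaN, 7), nm))
  }
  f <- haralick_features(C / sum(C))
  f[nm]
}

#' Normalized co-occurrence matrix features (6)
#'
#' Each row of the symmetric count matrix is normalized to a conditional
#' distribution before the global probability normalization; the same
#' Haralick-form indices are then computed, without correlation.
#' @inheritParams cooccurrence_features
#' @export
normalized_cooccurrence_features <- function(q, directions = offsets13()) {
  C <- glcm_counts(q, directions)
  nm <- c("second_angular_moment", "contrast", "entropy", "homogeneity",
          "inverse_difference_moment", "dissimilarity")
  if (sum(C) == 0) return(stats::setNames(rep(NaN, 6), nm))
  rs <- rowSums(C)
  Cn <- C
  Cn[rs > 0, ] <- C[rs > 0, , drop = FALSE] / rs[rs > 0]
  f <- haralick_features(Cn / sum(Cn), with_correlation = FALSE)
  f[nm]
}

# ---- voxel-alignment (run-length) ---------------------------------------

#' Run-length table of a quantized lesion
#'
#' A run is a set of consecutive, collinear in-mask voxels sharing a grey
#' level; out-of-mask voxels break runs. Runs are enumerated independently
#' per direction and pooled.
#' @return matrix with columns `level`, `length`, `count`
#' @keywords internal
run_table <- function(q, directions = offsets13()) {
  dm <- dim(q$levels)
  idx <- which(!is.na(q$levels))
  if (length(idx) == 0) return(cbind(level = integer(0), length = integer(0), count = integer(0)))
  pos <- arrayInd(idx, dm)
  lev <- q$levels[idx]
  acc <- list()
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ]
    step <- sum(d^2)
    t <- as.vector(pos %*% d)
    # perpendicular anchor of the line through each voxel (integer-exact)
    key <- pos * step - outer(t, d)
    kk <- (key[, 1] + 400) + (key[, 2] + 400) * 1e3 + (key[, 3] + 400) * 1e6
    o <- order(kk, t)
    newrun <- c(TRUE, kk[o][-1] != kk[o][-length(o)] |
                  t[o][-1] != t[o][-length(o)] + step |
                  lev[o][-1] != lev[o][-length(o)])
    rid <- cumsum(newrun)
    len <- tabulate(rid)
    rlev <- lev[o][newrun]
    acc[[r]] <- cbind(level = rlev, length = len)
  }
  all <- do.call(rbind, acc)
  ag <- stats::aggregate(list(count = rep(1L, nrow(all))),
                         by = list(level = all[, 1], length = all[, 2]), FUN = sum)
  as.matrix(ag[, c("level", "length", "count")])
}

# shared index formulas for the run-length and size-zone families;
# `size` is run length or zone size, `np` the number of (voxel, direction)
# slots for runs (in-mask voxels times directions) or voxels for zones
rl_style_indices <- function(level, size, count, np) {
  nr <- sum(count)
  c(
    sum(count / size^2) / nr,                     # short emphasis
    sum(count * size^2) / nr,                     # long/large emphasis
    sum(tapply(count, level, sum)^2) / nr,        # intensity variability
    sum(tapply(count, size, sum)^2) / nr,         # length/size variability
    nr / np,                                      # percentage
    sum(count / level^2) / nr,                    # low-intensity emphasis
    sum(count * level^2) / nr,                    # high-intensity emphasis
    sum(count / (level^2 * size^2)) / nr,         # low-intensity short
    sum(count * level^2 / size^2) / nr,           # high-intensity short
    sum(count * size^2 / level^2) / nr,           # low-intensity long
    sum(count * level^2 * size^2) / nr            # high-intensity long
  )
}

#' Voxel-alignment (run-length) matrix features (11)
#'
#' The 11 standard grey-level run-length indices: short/long-run emphasis,
#' intensity variability, run-length variability, run percentage, and the
#' low/high-intensity (short/long) run emphases.
#' @inheritParams cooccurrence_features
#' @export
voxel_alignment_features <- function(q, directions = offsets13()) {
  nm <- c("short_run_emphasis", "long_run_emphasis", "intensity_variability",
          "run_length_variability", "run_percentage",
          "low_intensity_run_emphasis", "high_intensity_run_emphasis",
          "low_intensity_short_run_emphasis", "high_intensity_short_run_emphasis",
          "low_intensity_long_run_emphasis", "high_intensity_long_run_emphasis")
  tab <- run_table(q, directions)
  if (nrow(tab) == 0) return(stats::setNames(rep(NaN, 11), nm))
  np <- sum(!is.na(q$levels)) * nrow(directions)
  stats::setNames(rl_style_indices(tab[, 1], tab[, 2], tab[, 3], np), nm)
}

#' Intensity size-zone matrix features (11)
#'
#' Zones are 26-connected components of equal grey level; indices mirror the
#' run-length family with zone size in place of run length.
#' @param q a `quantized_lesion`
#' @export
size_zone_features <- function(q) {
  nm <- c("short_zone_emphasis", "large_zone_emphasis", "intensity_variability",
          "size_zone_variability", "zone_percentage",
          "low_intensity_zone_emphasis", "high_intensity_zone_emphasis",
          "low_intensity_short_zone_emphasis", "high_intensity_short_zone_emphasis",
          "low_intensity_large_zone_emphasis", "high_intensity_large_zone_emphasis")
  lv <- q$levels
  present <- sort(unique(lv[!is.na(lv)]))
  if (length(present) == 0) return(stats::setNames(rep(NaN, 11), nm))
  rows <- list()
  for (l in present) {
    lab <- label_components26(!is.na(lv) & lv == l)
    if (max(lab) == 0) next
    sizes <- tabulate(lab[lab > 0])
    rows[[length(rows) + 1]] <- cbind(level = l, size = sizes)
  }
  all <- do.call(rbind, rows)
  ag <- stats::aggregate(list(count = rep(1L, nrow(all))),
                         by = list(level = all[, 1], size = all[, 2]), FUN = sum)
  np <- sum(!is.na(lv))
  stats::setNames(rl_style_indices(ag$level, ag$size, ag$count, np), nm)
}

# ---- neighbourhood intensity difference (NGTDM) -------------------------

ngtdm_table <- function(q) {
  lv <- q$levels
  inm <- !is.na(lv)
  lv0 <- lv; lv0[!inm] <- 0L
  nsum <- array(0, dim(lv)); ncnt <- array(0, dim(lv))
  off <- offsets26()
  for (r in seq_len(nrow(off))) {
    nsum <- nsum + shift3d(lv0, off[r, ], fill = 0L)
    ncnt <- ncnt + shift3d(inm, off[r, ], fill = FALSE)
  }
  valid <- inm & ncnt > 0
  abar <- nsum[valid] / ncnt[valid]
  lev <- lv[valid]
  L <- q$n_levels
  s <- rep(0, L); n <- rep(0, L)
  for (l in sort(unique(lev))) {
    sel <- lev == l
    s[l] <- sum(abs(l - abar[sel]))
    n[l] <- sum(sel)
  }
  list(s = s, n = n, N = sum(n))
}

#' Neighbourhood intensity-difference features (5)
#'
#' The Amadasun-King NGTDM indices: coarseness, contrast, busyness,
#' complexity, strength; 26-neighbour in-mask means. Coarseness is capped at
#' 1e6 (constant lesions); busyness of a constant lesion is 0.
#' @param q a `quantized_lesion`
#' @export
nid_features <- function(q) {
  tb <- ngtdm_table(q)
  s <- tb$s; n <- tb$n; N <- tb$N
  nm <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  if (N == 0) return(stats::setNames(rep(NaN, 5), nm))
  p <- n / N
  present <- which(p > 0)
  Ng <- length(present)
  coarse <- min(1 / (texture_eps + sum(p * s)), 1e6)
  if (Ng > 1) {
    ij <- expand.grid(i = present, j = present)
    pi <- p[ij$i]; pj <- p[ij$j]
    contr <- (sum(pi * pj * (ij$i - ij$j)^2) / (Ng * (Ng - 1))) * (sum(s) / N)
    den_busy <- sum(abs(ij$i * pi - ij$j * pj))
    busy <- if (den_busy > 0) sum(p * s) / den_busy else 0
    compl <- sum(abs(ij$i - ij$j) * (pi * s[ij$i] + pj * s[ij$j]) /
                   (N * (pi + pj)))
    strength <- sum((pi + pj) * (ij$i - ij$j)^2) / (texture_eps + sum(s))
  } else {
    contr <- 0; busy <- 0; compl <- 0; strength <- 0
  }
  stats::setNames(c(coarse, contr, busy, compl, strength), nm)
}

# ---- neighbourhood grey-level dependence --------------------------------

#' Neighbourhood grey-level dependence features (5)
#'
#' Dependence of a voxel = number of its 26 in-mask neighbours with the same
#' grey level (tolerance 0). Small/large-number emphases use (dependence+1)^2
#' so an isolated voxel (dependence 0) gives small-number emphasis 1.
#' @param q a `quantized_lesion`
#' @export
ngld_features <- function(q) {
  nm <- c("small_number_emphasis", "large_number_emphasis",
          "number_nonuniformity", "second_moment", "entropy")
  lv <- q$levels
  inm <- !is.na(lv)
  if (!any(inm)) return(stats::setNames(rep(NaN, 5), nm))
  dep <- array(0L, dim(lv))
  off <- offsets26()
  for (r in seq_len(nrow(off))) {
    nb <- shift3d(lv, off[r, ])
    dep <- dep + (!is.na(nb) & !is.na(lv) & nb == lv)
  }
  lev <- lv[inm]; s <- dep[inm]
  N <- length(lev)
  cnt <- stats::aggregate(list(q = rep(1L, N)),
                          by = list(level = lev, s = s), FUN = sum)
  Q <- cnt$q; sv <- cnt$s
  sne <- sum(Q / (sv + 1)^2) / N
  lne <- sum(Q * (sv + 1)^2) / N
  nnu <- sum(tapply(Q, sv, sum)^2) / N
  sm <- sum(Q^2) / N^2
  pq <- Q / N
  ent <- -sum(pq * log2(pq))
  stats::setNames(c(sne, lne, nnu, sm, ent), nm)
}

# ---- texture spectrum ---------------------------------------------------

#' Texture-spectrum features (2)
#'
#' He-Wang texture units over in-plane 3x3 neighbourhoods whose nine voxels
#' all lie in the mask: each of the eight neighbours is coded 0/1/2 (below /
#' equal / above the centre) and the unit number is the base-3 expansion in
#' fixed neighbour order. Max spectrum is the peak relative frequency;
#' black-white symmetry compares the spectrum with its intensity-inverted
#' mirror (unit j vs 6560 - j).
#' @param q a `quantized_lesion`
#' @export
texture_spectrum_features <- function(q) {
  nm <- c("max_spectrum", "black_white_symmetry")
  lv <- q$levels
  dm <- dim(lv)
  noff <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
                dy = c(-1, -1, -1, 0, 0, 1, 1, 1))
  units <- integer(0)
  for (z in seq_len(dm[3])) {
    sl <- lv[, , z]
    if (all(is.na(sl))) next
    code <- matrix(0, dm[1], dm[2])
    valid <- !is.na(sl)
    for (m in seq_len(8)) {
      d <- noff[m, ]
      nb <- matrix(NA_integer_, dm[1], dm[2])
      xs <- seq_len(dm[1]) - d[1]; ys <- seq_len(dm[2]) - d[2]
      okx <- xs >= 1 & xs <= dm[1]; oky <- ys >= 1 & ys <= dm[2]
      nb[okx, oky] <- sl[xs[okx], ys[oky]]
      valid <- valid & !is.na(nb)
      e <- sign(nb - sl) + 1L
      e[is.na(e)] <- 0L
      code <- code + e * 3L^(m - 1L)
    }
    units <- c(units, code[valid])
  }
  if (length(units) == 0) {
    out <- stats::setNames(rep(NaN, 2), nm)
    attr(out, "nan_reason") <- "lesion thinner than 3x3 in-plane"
    return(out)
  }
  S <- tabulate(units + 1L, nbins = 6561)
  tot <- sum(S)
  maxspec <- max(S) / tot
  j <- 0:3279
  bws <- 1 - sum(abs(S[j + 1] - S[6560 - j + 1])) / (2 * tot)
  stats::setNames(c(maxspec, bws), nm)
}

# ---- texture feature coding ---------------------------------------------

#' Gradient-class coded map used by the texture-feature-coding family
#'
#' For each in-mask voxel and each of the 13 axes with both opposite
#' neighbours in the mask, the two first-order level differences are
#' classified: 0 both zero (flat), 1 monotone/step (same sign or one zero),
#' 2 crest/valley (opposite signs). The voxel code is the sum over valid
#' axes (0..26). The coding depends on level differences only, so it is
#' invariant under a uniform level shift.
#' @return list with `code` values and `n` voxels considered
#' @keywords internal
tfc_code_map <- function(q) {
  lv <- q$levels
  code <- array(0L, dim(lv))
  nvalid <- array(0L, dim(lv))
  off <- offsets13()
  for (r in seq_len(nrow(off))) {
    d <- off[r, ]
    prv <- shift3d(lv, d)    # lv[x - d]
    nxt <- shift3d(lv, -d)   # lv[x + d]
    ok <- !is.na(lv) & !is.na(prv) & !is.na(nxt)
    if (!any(ok)) next
    d1 <- lv[ok] - prv[ok]
    d2 <- nxt[ok] - lv[ok]
    cls <- ifelse(d1 == 0 & d2 == 0, 0L, ifelse(d1 * d2 >= 0, 1L, 2L))
    code[ok] <- code[ok] + cls
    nvalid[ok] <- nvalid[ok] + 1L
  }
  keep <- !is.na(lv) & nvalid > 0
  list(map = ifelse(keep, code, NA_integer_), code = code[keep], n = sum(keep))
}

#' Texture-feature-coding features (4)
#'
#' Coarseness (fraction of flat-coded voxels), homogeneity (energy of the
#' code histogram), mean convergence (mean code normalized by the maximum
#' attainable code 26), and variance of the coded map.
#' @param q a `quantized_lesion`
#' @export
tfc_features <- function(q) {
  nm <- c("coarseness", "homogeneity", "mean_convergence", "variance")
  cm <- tfc_code_map(q)
  if (cm$n == 0) {
    out <- stats::setNames(rep(NaN, 4), nm)
    attr(out, "nan_reason") <- "no voxel has a complete neighbour pair"
    return(out)
  }
  p <- tabulate(cm$code + 1L, nbins = 27L) / cm$n
  mu <- mean(cm$code)
  stats::setNames(c(mean(cm$code == 0), sum(p^2), mu / 26,
                    mean((cm$code - mu)^2)), nm)
}

#' Texture-feature-coding co-occurrence features (8)
#'
#' Co-occurrence of the coded map over the 13 directions, probability
#' normalized; indices: second angular moment, contrast, entropy,
#' homogeneity, intensity (mean of the pair-averaged code), inverse
#' difference moment, correlation, and marginal variance.
#' @param q a `quantized_lesion`
#' @export
tfcc_features <- function(q) {
  nm <- c("second_angular_moment", "contrast", "entropy", "homogeneity",
          "intensity", "inverse_difference_moment", "correlation", "variance")
  cm <- tfc_code_map(q)
  if (cm$n == 0) return(stats::setNames(rep(NaN, 8), nm))
  fake_q <- list(levels = cm$map + 1L, n_levels = 27L)
  C <- glcm_counts(fake_q)
  if (sum(C) == 0) {
    out <- stats::setNames(rep(NaN, 8), nm)
    attr(out, "nan_reason") <- "coded map has no voxel pairs"
    return(out)
  }
  P <- C / sum(C)
  idx <- which(P > 0, arr.ind = TRUE)
  p <- P[idx]
  vi <- idx[, 1] - 1; vj <- idx[, 2] - 1   # actual code values
  sam <- sum(p^2)
  contrast <- sum((vi - vj)^2 * p)
  entropy <- -sum(p * log2(p))
  homog <- sum(p / (1 + abs(vi - vj)))
  intensity <- sum((vi + vj) / 2 * p)
  idm <- sum(p / (1 + (vi - vj)^2))
  mu_i <- sum(vi * p); mu_j <- sum(vj * p)
  s_i <- sqrt(sum((vi - mu_i)^2 * p)); s_j <- sqrt(sum((vj - mu_j)^2 * p))
  corr <- if (s_i > 0 && s_j > 0) sum((vi - mu_i) * (vj - mu_j) * p) / (s_i * s_j) else 0
  pm <- rowSums(P)
  vv <- seq_len(27) - 1
  mu_m <- sum(vv * pm)
  varr <- sum((vv - mu_m)^2 * pm)
  stats::setNames(c(sam, contrast, entropy, homog, intensity, idm, corr, varr), nm)
}
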