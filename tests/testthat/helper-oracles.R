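# Independent brute-force oracles for texture matrices and their features.
# These deliberately use naive elementwise loops and literal formula
# transcriptions, sharing no code with the package implementation.

# Ordered-pair enumeration: for every in-ROI pixel, look at its neighbor at
# +offset and at -offset, count both ordered pairs, normalize.
oracle_glcm <- function(labels, ng, direction, distance) {
  off <- switch(as.character(direction),
                "0" = c(0, 1), "45" = c(-1, 1), "90" = c(1, 0), "135" = c(1, 1))
  off <- off * distance
  P <- matrix(0, ng, ng)
  nr <- nrow(labels); nc <- ncol(labels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    a <- labels[r, c]
    if (is.na(a)) next
    for (sgn in c(1, -1)) {
      r2 <- r + sgn * off[1]; c2 <- c + sgn * off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      b <- labels[r2, c2]
      if (is.na(b)) next
      P[a, b] <- P[a, b] + 1
    }
  }
  if (sum(P) > 0) P <- P / sum(P)
  P
}

# Literal transcription of the 24 co-occurrence formulas with double loops.
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * P[i, j]
  sigma2 <- 0
  for (i in 1:ng) for (j in 1:ng) sigma2 <- sigma2 + P[i, j] * (i - mu)^2
  px <- rowSums(P)
  acc <- function(f) { s <- 0; for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j); s }
  lg <- function(x) if (x > 0) log2(x) else 0
  pd <- sapply(0:(ng - 1), function(k) acc(function(i, j) if (abs(i - j) == k) P[i, j] else 0))
  ps_ <- sapply(2:(2 * ng), function(k) acc(function(i, j) if (i + j == k) P[i, j] else 0))
  da <- sum((0:(ng - 1)) * pd)
  sa <- sum((2:(2 * ng)) * ps_)
  hxy <- -acc(function(i, j) P[i, j] * lg(P[i, j]))
  hxy1 <- -acc(function(i, j) P[i, j] * lg(px[i] * px[j]))
  hx <- -sum(sapply(1:ng, function(i) px[i] * lg(px[i])))
  c(autocorrelation = acc(function(i, j) i * j * P[i, j]),
    joint_average = mu,
    cluster_prominence = acc(function(i, j) P[i, j] * (i + j - 2 * mu)^4),
    cluster_shade = acc(function(i, j) P[i, j] * (i + j - 2 * mu)^3),
    cluster_tendency = acc(function(i, j) P[i, j] * (i + j - 2 * mu)^2),
    contrast = acc(function(i, j) P[i, j] * (i - j)^2),
    correlation = if (sigma2 > 0) (acc(function(i, j) i * j * P[i, j]) - mu^2) / sigma2 else 0,
    difference_average = da,
    difference_entropy = -sum(sapply(pd, function(p) p * lg(p))),
    difference_variance = sum(pd * ((0:(ng - 1)) - da)^2),
    dissimilarity = acc(function(i, j) P[i, j] * abs(i - j)),
    energy = acc(function(i, j) P[i, j]^2),
    entropy = hxy,
    homogeneity = acc(function(i, j) P[i, j] / (1 + abs(i - j))),
    idm = acc(function(i, j) P[i, j] / (1 + (i - j)^2)),
    idmn = acc(function(i, j) P[i, j] / (1 + (i - j)^2 / ng^2)),
    idn = acc(function(i, j) P[i, j] / (1 + abs(i - j) / ng)),
    inverse_variance = acc(function(i, j) if (i != j) P[i, j] / (i - j)^2 else 0),
    maximum_probability = max(P),
    sum_average = sa,
    sum_entropy = -sum(sapply(ps_, function(p) p * lg(p))),
    sum_variance = sum(ps_ * ((2:(2 * ng)) - sa)^2),
    variance = sigma2,
    imc1 = if (hx > 0) (hxy - hxy1) / hx else 0)
}

# Walk every line of the slice and record maximal runs by hand.
oracle_glrlm <- function(labels, ng, direction, max_len) {
  nr <- nrow(labels); nc <- ncol(labels)
  lines <- switch(as.character(direction),
    "0" = lapply(seq_len(nr), function(r) labels[r, ]),
    "90" = lapply(seq_len(nc), function(c) labels[, c]),
    "45" = lapply(2:(nr + nc), function(s) {
      rs <- seq(min(s - 1, nr), max(1, s - nc))   # row decreasing
      labels[cbind(rs, s - rs)]
    }),
    "135" = lapply((1 - nr):(nc - 1), function(d) {
      rs <- seq(max(1, 1 - d), min(nr, nc - d))   # row increasing
      labels[cbind(rs, rs + d)]
    }))
  R <- matrix(0, ng, max_len)
  for (line in lines) {
    run_val <- NA; run_len <- 0
    flush <- function() {
      if (!is.na(run_val) && run_len > 0) R[run_val, run_len] <<- R[run_val, run_len] + 1
    }
    for (v in line) {
      if (is.na(v)) { flush(); run_val <- NA; run_len <- 0 }
      else if (!is.na(run_val) && v == run_val) run_len <- run_len + 1
      else { flush(); run_val <- v; run_len <- 1 }
    }
    flush()
  }
  R
}

oracle_glrlm_features <- function(R, n_vox) {
  nr_ <- sum(R)
  s <- list(SRE = 0, LRE = 0, LGLRE = 0, HGLRE = 0, SRLGLE = 0, SRHGLE = 0,
            LRLGLE = 0, LRHGLE = 0)
  for (i in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    r <- R[i, l]
    s$SRE <- s$SRE + r / l^2;        s$LRE <- s$LRE + r * l^2
    s$LGLRE <- s$LGLRE + r / i^2;    s$HGLRE <- s$HGLRE + r * i^2
    s$SRLGLE <- s$SRLGLE + r / (i^2 * l^2)
    s$SRHGLE <- s$SRHGLE + r * i^2 / l^2
    s$LRLGLE <- s$LRLGLE + r * l^2 / i^2
    s$LRHGLE <- s$LRHGLE + r * i^2 * l^2
  }
  p <- R / nr_
  mi <- 0; ml <- 0
  for (i in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    mi <- mi + p[i, l] * i; ml <- ml + p[i, l] * l
  }
  glv <- 0; rlv <- 0
  for (i in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    glv <- glv + p[i, l] * (i - mi)^2; rlv <- rlv + p[i, l] * (l - ml)^2
  }
  c(SRE = s$SRE / nr_, LRE = s$LRE / nr_,
    GLN = sum(rowSums(R)^2) / nr_, RLN = sum(colSums(R)^2) / nr_,
    RP = nr_ / n_vox,
    LGLRE = s$LGLRE / nr_, HGLRE = s$HGLRE / nr_,
    SRLGLE = s$SRLGLE / nr_, SRHGLE = s$SRHGLE / nr_,
    LRLGLE = s$LRLGLE / nr_, LRHGLE = s$LRHGLE / nr_,
    GLV = glv, RLV = rlv)
}

# Build a gray_level_map around a given single-slice label matrix, bypassing
# discretization (labels already in 1..ng; NA outside ROI).
gray_map_from_labels <- function(labels, ng) {
  structure(list(labels = array(labels, c(1L, nrow(labels), ncol(labels))),
                 n_bins = as.integer(ng),
                 breaks = seq(0.5, ng + 0.5, by = 1),
                 degenerate = FALSE,
                 in_plane_spacing = 1, slice_thickness = 4),
            class = "gray_level_map")
}

# Random single-slice label map with NA holes, for oracle-equivalence sweeps.
random_label_map <- function(nr = 8, nc = 8, ng = 4, p_na = 0.2) {
  m <- matrix(sample(seq_len(ng), nr * nc, replace = TRUE), nr, nc)
  m[stats::runif(nr * nc) < p_na] <- NA
  m
}

# Textbook unweighted product-limit estimator (events precede censorings at
# tied times), for KM oracle equivalence.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1; out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    t <- ut[k]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out[k] <- s
  }
  data.frame(time = ut, surv = out)
}
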