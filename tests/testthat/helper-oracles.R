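# Independent oracles: literal transliterations used to cross-check the
# package implementation. These deliberately share no code with R/ — the
# distance endpoints are hard-coded here rather than read from the shipped
# definition file, and each formula is written out directly.

# random plausible landmark set: template plus Gaussian jitter (sd in px at
# interocular 100); jitter small enough that no slope denominator vanishes
random_landmarks <- function(sd = 2, source_id = "rnd") {
  base <- make_template()$points
  landmarks51(base + matrix(stats::rnorm(102, sd = sd), 51L, 2L),
              source_id = source_id)
}

# brute-force 2x3 affine product, one point at a time
oracle_apply_transform <- function(m, pts) {
  out <- matrix(NA_real_, nrow(pts), 2L)
  for (i in seq_len(nrow(pts))) {
    v <- c(pts[i, 1L], pts[i, 2L], 1)
    out[i, 1L] <- sum(m[1L, ] * v)
    out[i, 2L] <- sum(m[2L, ] * v)
  }
  out
}

# pairwise edge-sum perimeter
oracle_perimeter <- function(pts) {
  n <- nrow(pts)
  s <- 0
  for (i in seq_len(n - 1L))
    s <- s + sqrt((pts[i, 1L] - pts[i + 1L, 1L])^2 +
                    (pts[i, 2L] - pts[i + 1L, 2L])^2)
  s + sqrt((pts[1L, 1L] - pts[n, 1L])^2 + (pts[1L, 2L] - pts[n, 2L])^2)
}

# literal re-evaluation of the seven confusion-matrix statistics
oracle_metrics <- function(tp, tn, fp, fn) {
  c(Acc = (tp + tn) / (tp + tn + fp + fn),
    Rec = tp / (tp + fn),
    Prec = tp / (tp + fp),
    F1s = 2 * tp / (2 * tp + fp + fn),
    TNR = tn / (tn + fp),
    FNR = fn / (fn + tp),
    FPR = fp / (fp + tn))
}

# literal transliteration of the full feature table from a tilt-corrected
# 51-point matrix (0-based P indices hard-coded)
oracle_features <- function(pts) {
  P <- function(i) pts[i + 1L, ]
  d <- function(i, j) {
    a <- P(i); b <- P(j)
    sqrt((a[1L] - b[1L])^2 + (a[2L] - b[2L])^2)
  }
  ang <- function(i, j) {
    a <- P(i); b <- P(j)
    v <- atan2(a[2L] - b[2L], a[1L] - b[1L]) * 180 / pi
    if (v > 90) v <- v - 180
    if (v <= -90) v <- v + 180
    abs(v)
  }
  slp <- function(i, j) {
    a <- P(i); b <- P(j)
    (a[2L] - b[2L]) / (a[1L] - b[1L])
  }
  peri <- function(idx) oracle_perimeter(pts[idx + 1L, , drop = FALSE])
  mx <- function(x, y) max(x / y, y / x)

  yref <- (P(10)[2L] + P(19)[2L]) / 2
  L <- mean(abs(yref - pts[1:5, 2L]))
  M <- mean(abs(yref - pts[6:10, 2L]))
  A <- d(10, 19); Bl <- d(10, 13); Br <- d(16, 19); C <- d(13, 16)
  D <- d(11, 15); E <- d(18, 20); F <- d(22, 28); G <- d(22, 34)
  H <- d(2, 12); I <- d(7, 17); J <- d(10, 28); K <- d(19, 34)
  Nl <- d(10, 12); Nr <- d(19, 17); Ol <- d(10, 14); Or <- d(19, 21)
  Pl <- d(28, 37); Pu <- d(28, 31); Ql <- d(34, 37); Qu <- d(34, 31)
  R <- d(22, 10); S <- d(22, 19); T <- d(0, 28); U <- d(9, 34)
  Vl <- d(28, 13); Vr <- d(34, 16); W <- d(28, 34); X <- d(25, 31)
  Wl <- peri(c(28, 29, 30, 31, 37, 38, 39))
  Wr <- peri(c(31, 32, 33, 34, 35, 36, 37))
  N <- (Nl + Nr) / 2; O <- (Ol + Or) / 2

  c(f0 = ang(0, 9), f1 = ang(2, 7), f2 = ang(4, 5), f3 = mx(L, M),
    f4 = slp(0, 9), f5 = slp(2, 7), f6 = slp(4, 5), f7 = ang(10, 19),
    f8 = mx(Bl, Br), f9 = mx(D, E), f10 = mx(H, I), f11 = mx(N, O),
    f12 = mx(Nl, Or), f13 = mx(Nr, Ol), f14 = ang(28, 34), f15 = mx(F, G),
    f16 = mx(Pl, Ql), f17 = mx(Pu, Qu),
    f18 = max(Vl / A, Vr / A), f19 = max(Pl / W, Ql / W),
    f20 = max(Pu / W, Qu / W), f21 = max(Wl / W, Wr / W),
    f22 = ang(23, 27), f23 = ang(22, 37), f24 = mx(J, K),
    f25 = max(T / A, U / A), f26 = max(R / A, S / A),
    f27 = C / A, f28 = X / A)
}

# indices (1-based into f0..f28) of the paired max(x/y, y/x) features, which
# equal 1 exactly on a symmetric face
PAIRED_MAX <- c(3, 8, 9, 10, 11, 12, 13, 15, 16, 17, 24) + 1L
# angle features expected 0 on a level symmetric face, and the midline one
HORIZONTAL_ANGLES <- c(0, 1, 2, 7, 14, 22) + 1L
SLOPES <- c(4, 5, 6) + 1L

# small labeled toy: two well-separated Gaussian blobs in p dims
toy_blobs <- function(n_per = 20, p = 5, gap = 10, sd = 0.5, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * p, 0, sd), n_per),
             matrix(stats::rnorm(n_per * p, gap, sd), n_per))
  labeled_dataset(x, rep(c("0", "1"), each = n_per))
}
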