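# Independent brute-force oracles shared across test files. These stay
# deliberately naive (explicit loops, direct formulas) so they cannot share a
# code path with the implementation they check.

# Sum of continuous Gaussians evaluated on the pixel grid, max-normalized.
oracle_gaze_map <- function(xs, ys, sigma, img_w, img_h) {
  out <- matrix(0, img_h, img_w)
  for (k in seq_along(xs)) {
    for (i in seq_len(img_h)) for (j in seq_len(img_w)) {
      d2 <- (j - 1 - xs[k])^2 + (i - 1 - ys[k])^2
      out[i, j] <- out[i, j] + exp(-d2 / (2 * sigma^2))
    }
  }
  if (max(out) > 0) out <- out / max(out)
  out
}

# Triple-loop class-activation map for one class (pre-sigmoid, pre-resize).
oracle_cam_raw <- function(fmap, wvec) {
  d <- dim(fmap)
  raw <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3]))
    raw[i, j] <- raw[i, j] + max(wvec[c], 0) * fmap[i, j, c]
  raw
}

# Direct-formula binary metrics (independent spelling of the definitions).
oracle_metrics <- function(tp, fp, tn, fn) {
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  c(acc = (tp + tn) / (tp + fp + tn + fn),
    pre = pre, rec = rec,
    f1 = if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0,
    mcc = if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0)
}

oracle_kappa <- function(cm) {
  tot <- sum(cm)
  p0 <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  (p0 - pe) / (1 - pe)
}

# All-pairs AUC with midrank tie handling: wins + half-ties over all
# positive-negative pairs.
oracle_auc_pairs <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  wins <- 0
  for (a in sp) for (b in sn)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(sp) * length(sn))
}

# A small cached synthetic dataset + quickly trained models for method tests.
local_fixture_env <- new.env()

small_dataset <- function() {
  if (is.null(local_fixture_env$data))
    local_fixture_env$data <- synthesize_polyp_data(
      phantom_spec(n_patients = 8, lesions_per_patient = c(3, 4)),
      scanpath_spec(), seed = 11)
  local_fixture_env$data
}

small_fit <- function() {
  if (is.null(local_fixture_env$fit))
    local_fixture_env$fit <- gazecam(
      small_dataset(), lambda_gaze = 1,
      control = gazecam_control(max_epochs = 3), seed = 5)
  local_fixture_env$fit
}
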