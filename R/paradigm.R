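#' Build a block cue-reactivity paradigm
#'
#' Constructs the timing table of a blocked cue-exposure task: epochs of
#' fixed length, each containing alternating blocks of the four task
#' conditions (Drug, Neutral, Blur, Rest). With the defaults -- six 120-s
#' epochs of 24-s blocks -- the task lasts 12 minutes and each epoch has five
#' block slots, one more than there are conditions; `epoch_fill` decides how
#' the extra slot is used.
#'
#' @param n_epochs Number of epochs (default 6).
#' @param block_s Block duration in seconds (default 24).
#' @param epoch_s Epoch duration in seconds (default 120). Must be an integer
#'   multiple of `block_s`.
#' @param order Condition order within an epoch (default
#'   `c("Drug", "Neutral", "Blur", "Rest")`).
#' @param epoch_fill How to fill epoch slots beyond `length(order)`:
#'   `"repeat_rest"` (default) pads each epoch with extra Rest blocks;
#'   `"cycle"` keeps cycling through `order` across slots and epochs.
#' @return A `block_paradigm`: a tibble with columns `condition`, `onset_s`,
#'   `duration_s` and attribute `total_duration_s`.
#' @examples
#' p <- build_paradigm()
#' attr(p, "total_duration_s") # 720 s = 12 min
#' @export
build_paradigm <- function(n_epochs = 6, block_s = 24, epoch_s = 120,
                           order = c("Drug", "Neutral", "Blur", "Rest"),
                           epoch_fill = c("repeat_rest", "cycle")) {
  epoch_fill <- match.arg(epoch_fill)
  if (n_epochs < 1) abort("`n_epochs` must be >= 1.")
  if (block_s <= 0) abort("`block_s` must be positive.")
  slots <- epoch_s / block_s
  if (abs(slots - round(slots)) > 1e-9) {
    abort("`epoch_s` must be an integer multiple of `block_s`.")
  }
  slots <- as.integer(round(slots))
  if (slots < length(order)) {
    abort("epoch too short for the requested condition order.")
  }
  conds <- switch(epoch_fill,
    repeat_rest = rep(
      c(order, rep("Rest", slots - length(order))),
      times = n_epochs
    ),
    cycle = rep(order, length.out = slots * n_epochs)
  )
  n_blocks <- slots * n_epochs
  blocks <- tibble(
    condition = conds,
    onset_s = (seq_len(n_blocks) - 1) * block_s,
    duration_s = block_s
  )
  new_block_paradigm(blocks)
}

new_block_paradigm <- function(blocks) {
  blocks <- as_tibble(blocks)
  stopifnot(all(c("condition", "onset_s", "duration_s") %in% names(blocks)))
  if (any(blocks$duration_s <= 0)) abort("block durations must be positive.")
  o <- order(blocks$onset_s)
  blocks <- blocks[o, ]
  ends <- blocks$onset_s + blocks$duration_s
  if (nrow(blocks) > 1 &&
      any(blocks$onset_s[-1] < ends[-nrow(blocks)] - 1e-9)) {
    abort("blocks must not overlap.")
  }
  structure(
    blocks,
    total_duration_s = max(ends),
    class = c("block_paradigm", class(blocks))
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF used to convolve condition boxcars: a gamma-density
#' response peaking near 6 s minus a 1/6-amplitude undershoot peaking near
#' 16 s (both with unit dispersion), rescaled to unit peak amplitude.
#'
#' @param t_s Time(s) in seconds since stimulus onset; values < 0 return 0.
#' @param peak_delay_s,undershoot_delay_s Gamma shape parameters (seconds).
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return Amplitudes at `t_s`, unit peak.
#' @export
hrf <- function(t_s, peak_delay_s = 6, undershoot_delay_s = 16,
                undershoot_ratio = 6) {
  raw <- function(t) {
    ifelse(t < 0, 0,
      dgamma(t, shape = peak_delay_s, scale = 1) -
        dgamma(t, shape = undershoot_delay_s, scale = 1) / undershoot_ratio
    )
  }
  grid <- seq(0, 32, by = 0.01)
  peak <- max(raw(grid))
  raw(t_s) / peak
}

#' Build an HRF-convolved design matrix
#'
#' Converts a block paradigm into a first-level GLM design: one boxcar per
#' modeled condition convolved with the canonical [hrf()] and sampled at
#' volume acquisition times `i * tr_s` (i = 0, ..., n-1), plus six motion
#' covariates and an intercept. Rest is treated as the implicit baseline and
#' is not given a regressor. All-zero motion columns are dropped (recorded in
#' the `dropped` attribute) so the design stays full rank.
#'
#' @param paradigm A `block_paradigm`.
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of volumes acquired.
#' @param motion Optional n_volumes x 6 matrix of motion parameters
#'   (x, y, z, yaw, pitch, roll). Default zero (dropped).
#' @param conditions Conditions to model (default all except Rest).
#' @param oversample Microtime resolution for the convolution, samples per
#'   TR (default 16).
#' @return A `design_matrix`: list with elements `X` (named matrix),
#'   `conditions`, `tr_s`, `n_volumes`.
#' @export
build_design <- function(paradigm, tr_s, n_volumes, motion = NULL,
                         conditions = NULL, oversample = 16) {
  stopifnot(inherits(paradigm, "block_paradigm"))
  conditions <- conditions %||%
    setdiff(unique(paradigm$condition), "Rest")
  dt <- tr_s / oversample
  total <- max(attr(paradigm, "total_duration_s"), n_volumes * tr_s)
  tgrid <- seq(0, total + 32, by = dt)
  hr <- hrf(seq(0, 32, by = dt))
  vol_t <- (seq_len(n_volumes) - 1) * tr_s
  cols <- lapply(conditions, function(cond) {
    box <- rep(0, length(tgrid))
    bl <- paradigm[paradigm$condition == cond, ]
    for (i in seq_len(nrow(bl))) {
      on <- bl$onset_s[i]
      off <- on + bl$duration_s[i]
      box[tgrid >= on & tgrid < off] <- 1
    }
    if (!any(box > 0)) abort(paste0("condition has no blocks: ", cond))
    conv <- stats::convolve(box, rev(hr), type = "open")[seq_along(tgrid)] * dt
    stats::approx(tgrid, conv, xout = vol_t, rule = 2)$y
  })
  X <- do.call(cbind, cols)
  colnames(X) <- conditions
  dropped <- character()
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes || ncol(motion) != 6L) {
      abort("`motion` must be an n_volumes x 6 matrix.")
    }
    if (!all(is.finite(motion))) abort("motion parameters must be finite.")
    colnames(motion) <- paste0("motion_", c("x", "y", "z",
                                            "yaw", "pitch", "roll"))
    keep <- colSums(abs(motion)) > 0
    dropped <- colnames(motion)[!keep]
    if (any(keep)) X <- cbind(X, motion[, keep, drop = FALSE])
  }
  X <- cbind(X, intercept = 1)
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank deficient.")
  structure(
    list(X = X, conditions = conditions, tr_s = tr_s,
         n_volumes = n_volumes),
    dropped = dropped,
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf(
    "<design_matrix> %d volumes x %d regressors (%s)\n",
    x$n_volumes, ncol(x$X), paste(colnames(x$X), collapse = ", ")
  ))
  invisible(x)
}
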