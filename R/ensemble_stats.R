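# Ensemble-level genus analytics: per-position summaries of member genus
# traces (with optional Gaussian smoothing) and genus-versus-length
# regression.

#' Per-position summary of ensemble genus traces
#'
#' For an ensemble of structures sharing one backbone length, computes the
#' mean, mode, standard deviation, minimum and maximum of the members' genus
#' traces at every position, plus a Gaussian-smoothed mean and standard
#' deviation (1-D kernel, width \code{sigma}; \code{sigma = 0} disables
#' smoothing).  Mode ties are broken toward the smaller genus.  Positions
#' recorded as \code{NA} (missing data) are excluded position-wise from the
#' statistics and from the smoothing windows.
#'
#' @param x a \code{fold_ensemble}, a list of \code{\link{rna_structure}}
#'   objects, or a numeric matrix of traces (positions in columns, one row
#'   per member).
#' @param sigma smoothing width in backbone positions (default 1).
#' @return object of class \code{trace_summary}: data-frame-like list with
#'   \code{position}, \code{mean}, \code{mode}, \code{sd}, \code{min},
#'   \code{max}, \code{smoothed_mean}, \code{smoothed_sd}.
#' @export
ensemble_trace_summary <- function(x, sigma = 1) {
  traces <- trace_matrix(x)
  if (!nrow(traces)) stop("empty ensemble", call. = FALSE)
  stat <- function(f) apply(traces, 2L, f)
  means <- stat(function(v) mean(v, na.rm = TRUE))
  sds <- stat(function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1L) stats::sd(v) else 0
  })
  modes <- stat(trace_mode)
  mins <- stat(function(v) suppressWarnings(min(v, na.rm = TRUE)))
  maxs <- stat(function(v) suppressWarnings(max(v, na.rm = TRUE)))
  mins[!is.finite(mins)] <- NA; maxs[!is.finite(maxs)] <- NA
  structure(
    list(position = seq_len(ncol(traces)), mean = means, mode = modes,
         sd = sds, min = mins, max = maxs,
         smoothed_mean = gaussian_smooth(means, sigma),
         smoothed_sd = gaussian_smooth(sds, sigma),
         sigma = sigma, n_members = nrow(traces)),
    class = "trace_summary")
}

trace_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  members <- if (inherits(x, "fold_ensemble")) ensemble_structures(x)
             else x
  stopifnot(is.list(members), length(members) >= 1L)
  lens <- vapply(members, function(s) s$length, 0L)
  if (length(unique(lens)) != 1L)
    stop("ensemble members have mixed backbone lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  do.call(rbind, lapply(members, function(s) as.integer(genus_trace(s))))
}

# per-position mode; ties broken toward the smaller genus
trace_mode <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_integer_)
  tab <- table(v)
  as.integer(names(tab)[which.max(tab)])  # names sorted ascending: first max
}

#' Gaussian smoothing of a positional signal
#'
#' 1-D Gaussian kernel convolution (radius \eqn{\lceil 4\sigma \rceil}) with
#' reflection padding at the boundaries; \code{NA} entries are excluded from
#' the windows (normalized convolution) and stay \code{NA} in the output.
#' \code{sigma = 0} returns the input unchanged.
#'
#' @param v numeric vector.
#' @param sigma kernel width, in positions.
#' @return numeric vector of the same length.
#' @export
gaussian_smooth <- function(v, sigma = 1) {
  if (sigma <= 0 || length(v) < 2L) return(v)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  kern <- stats::dnorm(seq.int(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  n <- length(v)
  # reflection padding with edge duplication: (v[r]..v[1] | v | v[n]..)
  idx <- c(rev(seq_len(min(r, n))), seq_len(n),
           n + 1L - seq_len(min(r, n)))
  while (length(idx) < n + 2L * r)  # degenerate short inputs: keep reflecting
    idx <- c(idx[1], idx, idx[length(idx)])
  pad <- v[idx]
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(v[i])) { out[i] <- NA_real_; next }
    win <- pad[i:(i + 2L * r)]
    w <- kern[!is.na(win)]
    out[i] <- sum(win[!is.na(win)] * w) / sum(w)
  }
  out
}

#' @export
print.trace_summary <- function(x, ...) {
  cat("Ensemble genus-trace summary over", x$n_members, "members,",
      length(x$position), "positions (sigma =", x$sigma, ")\n")
  cat("  final mean genus:", format(x$mean[length(x$mean)], digits = 4),
      "\n")
  utils::str(x[c("mean", "mode", "sd", "min", "max")], vec.len = 4)
  invisible(x)
}

#' @export
as.data.frame.trace_summary <- function(x, ...) {
  data.frame(position = x$position, mean = x$mean, mode = x$mode,
             sd = x$sd, min = x$min, max = x$max,
             smoothed_mean = x$smoothed_mean, smoothed_sd = x$smoothed_sd)
}

#' @export
plot.trace_summary <- function(x, ...) {
  graphics::plot(x$position, x$smoothed_mean, type = "l",
                 ylim = range(c(x$min, x$max), na.rm = TRUE),
                 xlab = "position", ylab = "genus", ...)
  graphics::lines(x$position, x$mode, type = "s", lty = 2)
  graphics::polygon(
    c(x$position, rev(x$position)),
    c(x$smoothed_mean - x$smoothed_sd,
      rev(x$smoothed_mean + x$smoothed_sd)),
    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  invisible(x)
}

#' Genus-versus-length linear regression
#'
#' Ordinary least squares of mean ensemble genus on sequence length,
#' reporting the slope per ribonucleotide, intercept, \eqn{r^2} and the
#' slope standard error; optionally through the origin.
#'
#' @param lengths sequence lengths (positive).
#' @param mean_genus mean ensemble genus per sequence.
#' @param zero_intercept force the intercept to 0.
#' @return object of class \code{genus_fit} wrapping the underlying
#'   \code{\link[stats]{lm}} fit, with elements \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{slope_se}.
#' @examples
#' fit_length_genus(c(100, 200, 300), c(1, 2, 3))
#' @export
fit_length_genus <- function(lengths, mean_genus, zero_intercept = FALSE) {
  stopifnot(length(lengths) == length(mean_genus), length(lengths) >= 2L,
            all(lengths > 0))
  if (length(unique(lengths)) < 2L)
    stop("degenerate regression: all lengths are equal", call. = FALSE)
  df <- data.frame(d = as.numeric(lengths), g = as.numeric(mean_genus))
  fit <- if (zero_intercept) stats::lm(g ~ 0 + d, data = df)
         else stats::lm(g ~ d, data = df)
  # collinear records are legitimate input (exact fits); summary.lm's
  # "essentially perfect fit" warning is noise here
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(
    list(slope = unname(co["d", "Estimate"]),
         intercept = if (zero_intercept) 0
                     else unname(co["(Intercept)", "Estimate"]),
         r_squared = sm$r.squared,
         slope_se = unname(co["d", "Std. Error"]),
         zero_intercept = zero_intercept, n = nrow(df), lm = fit),
    class = "genus_fit")
}

#' @export
print.genus_fit <- function(x, ...) {
  cat("Genus-length fit (n = ", x$n, "): g = ",
      format(x$slope, digits = 4), " d",
      if (!x$zero_intercept)
        paste0(if (x$intercept >= 0) " + " else " - ",
               format(abs(x$intercept), digits = 4)),
      "\n", sep = "")
  cat("  r^2 = ", format(x$r_squared, digits = 4),
      ", slope std. err. = ", format(x$slope_se, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.genus_fit <- function(object, ...)
  c(slope = object$slope, intercept = object$intercept)
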