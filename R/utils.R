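# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Sliding-window grid along one chromosome
#'
#' Window starts are `1, 1 + step, 1 + 2*step, ...` and a window is emitted
#' while it fits entirely inside the chromosome
#' (`start + window_size - 1 <= chrom_length`).
#'
#' @param chrom_length chromosome length in bp.
#' @param window_size window width in bp.
#' @param step step between window starts in bp.
#' @return integer vector of window start positions (possibly empty).
#' @keywords internal
window_starts <- function(chrom_length, window_size, step) {
  stopifnot(window_size >= step, step >= 1)
  if (chrom_length < window_size) return(integer(0))
  seq.int(1L, as.integer(chrom_length - window_size + 1L), by = as.integer(step))
}

# Map site positions to the (1-based) indices of every grid window covering
# them.  Returns list(site = i, win = k) index pairs; a site can fall in up
# to ceiling(window_size/step) windows.
site_window_pairs <- function(pos, window_size, step, n_windows) {
  if (n_windows == 0L || length(pos) == 0L)
    return(list(site = integer(0), win = integer(0)))
  ratio <- ceiling(window_size / step)
  site_idx <- integer(0)
  win_idx <- integer(0)
  j_hi <- (pos - 1) %/% step            # largest candidate window offset
  for (m in seq_len(ratio) - 1L) {
    j <- j_hi - m
    ok <- j >= 0 & j <= (n_windows - 1L) & pos <= j * step + window_size
    if (any(ok)) {
      site_idx <- c(site_idx, which(ok))
      win_idx <- c(win_idx, as.integer(j[ok]) + 1L)
    }
  }
  list(site = site_idx, win = win_idx)
}

# Stop unless x is a single finite number.
assert_scalar_number <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
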