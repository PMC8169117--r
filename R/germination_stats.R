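#' Germination-time trait summary
#'
#' Computes the germination traits used throughout the analyses: CV
#' (sample standard deviation / mean, over germinated seeds only), mean,
#' mode and percentage germination. Times are binned into right-closed
#' intervals `((k-1)*bin_width, k*bin_width]` anchored at 0 and the mode is
#' the label (right edge) of the most populated bin, so for day-binned data
#' with `bin_width = 1` the mode is the most frequent day; ties are broken
#' towards the earliest bin. The reporting filter withholds CV/mean/mode
#' unless at least `min_germinated` seeds germinated (default: 1% of
#' `n_sown`, i.e. more than nine seeds out of 1000).
#'
#' @param times germination times of the germinated seeds (positive).
#' @param n_sown number of seeds sown (>= `length(times)`).
#' @param bin_width histogram bin width for the mode (default 1, mirroring
#'   daily scoring).
#' @param min_germinated minimal number of germinated seeds for the summary
#'   to be reportable; default `ceiling(n_sown / 100)`.
#' @return A `trait_summary`: list with `cv`, `mean`, `mode`,
#'   `pct_germination`, `n_germinated`, `n_sown`, `reportable`. With no
#'   germinated seeds, cv/mean/mode are `NA` and `pct_germination` is 0.
#' @export
summarize_times <- function(times, n_sown, bin_width = 1,
                            min_germinated = ceiling(n_sown / 100)) {
  times <- as.numeric(times)
  times <- times[!is.na(times)]
  if (any(times <= 0) || any(!is.finite(times)))
    stop("germination times must be positive and finite")
  if (n_sown < length(times))
    stop("n_sown must be at least the number of germinated seeds")
  if (!(bin_width > 0)) stop("bin_width must be > 0")
  n_g <- length(times)
  reportable <- n_g >= max(min_germinated, 1)
  if (n_g == 0) {
    out <- list(cv = NA_real_, mean = NA_real_, mode = NA_real_,
                pct_germination = 0, n_germinated = 0L, n_sown = n_sown,
                reportable = FALSE)
    return(structure(out, class = "trait_summary"))
  }
  m <- mean(times)
  cv <- if (n_g > 1) stats::sd(times) / m else 0
  # right-closed bins anchored at 0; label = right edge (day semantics)
  bins <- ceiling(times / bin_width - 1e-12)
  tab <- table(bins)
  mode_bin <- as.numeric(names(tab)[which.max(tab)])  # which.max: first max
  structure(list(cv = cv, mean = m, mode = mode_bin * bin_width,
                 pct_germination = 100 * n_g / n_sown,
                 n_germinated = n_g, n_sown = n_sown,
                 reportable = reportable),
            class = "trait_summary")
}

#' @export
print.trait_summary <- function(x, ...) {
  cat(sprintf(paste0("germination traits: %d/%d germinated (%.1f%%)",
                     if (x$reportable) "" else " [not reportable]", "\n"),
              x$n_germinated, x$n_sown, x$pct_germination))
  if (x$n_germinated > 0)
    cat(sprintf("  CV %.4g, mean %.4g, mode %.4g\n", x$cv, x$mean, x$mode))
  invisible(x)
}

#' Construct and validate a day-binned germination count table
#'
#' Records of daily germination counts per plate: one row per (line,
#' replicate parent plant, plate, day). Within a plate, days must be
#' strictly increasing and total germinated seeds cannot exceed seeds sown.
#'
#' @param df data frame with columns `line_id`, `replicate_id`, `plate_id`,
#'   `day`, `n_germinated`, `n_sown`.
#' @return The validated data frame with class `germination_counts`.
#' @export
germination_counts <- function(df) {
  req <- c("line_id", "replicate_id", "plate_id", "day", "n_germinated", "n_sown")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  df$day <- as.integer(df$day)
  df$n_germinated <- as.integer(df$n_germinated)
  df$n_sown <- as.integer(df$n_sown)
  if (any(df$day < 1)) stop("days must be >= 1")
  if (any(df$n_germinated < 0)) stop("counts must be non-negative")
  for (pl in split(df, df$plate_id)) {
    if (is.unsorted(pl$day, strictly = TRUE))
      stop("days not strictly increasing within plate ", pl$plate_id[1])
    if (length(unique(pl$n_sown)) != 1)
      stop("inconsistent n_sown within plate ", pl$plate_id[1])
    if (sum(pl$n_germinated) > pl$n_sown[1])
      stop("more seeds germinated than sown on plate ", pl$plate_id[1])
  }
  class(df) <- unique(c("germination_counts", class(df)))
  df
}

#' Per-plate trait summaries from day-binned counts
#'
#' Expands each plate's daily counts to per-seed integer day values,
#' summarizes them with [summarize_times()] (`bin_width = 1` day), and
#' excludes plates on which fewer than `min_plate_germinated` seeds
#' germinated (default 10) from downstream aggregation (their traits are
#' still computed but flagged `excluded`).
#'
#' @param table a [germination_counts()] data frame.
#' @param min_plate_germinated plate-level inclusion filter.
#' @return data frame with one row per plate: ids, `cv`, `mean`, `mode`,
#'   `pct_germination`, `n_germinated`, `n_sown`, `excluded`.
#' @export
summarize_counts <- function(table, min_plate_germinated = 10) {
  table <- germination_counts(as.data.frame(table))
  plates <- split(table, table$plate_id)
  rows <- lapply(plates, function(pl) {
    days <- rep(pl$day, pl$n_germinated)
    n_sown <- pl$n_sown[1]
    s <- summarize_times(days, n_sown = n_sown, bin_width = 1,
                         min_germinated = 1)
    data.frame(line_id = pl$line_id[1], replicate_id = pl$replicate_id[1],
               plate_id = pl$plate_id[1],
               cv = s$cv, mean = s$mean, mode = s$mode,
               pct_germination = s$pct_germination,
               n_germinated = s$n_germinated, n_sown = n_sown,
               excluded = s$n_germinated < min_plate_germinated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$line_id, out$replicate_id, out$plate_id), , drop = FALSE]
}

#' Line-level aggregation of per-plate traits
#'
#' A line's CV (and mean, mode, percentage germination) is the unweighted
#' mean of the per-plate values over its included plates, mirroring
#' replicate seed batches from separate parent plants.
#'
#' @param per_plate data frame as produced by [summarize_counts()]
#'   (optionally several lines at once).
#' @return data frame with one row per line and a `n_plates` column
#'   counting the contributing plates; lines with zero included plates are
#'   dropped with a message.
#' @export
aggregate_line <- function(per_plate) {
  keep <- per_plate[!per_plate$excluded, , drop = FALSE]
  dropped <- setdiff(unique(per_plate$line_id), unique(keep$line_id))
  if (length(dropped))
    message("line(s) excluded (no plate with enough germinated seeds): ",
            paste(dropped, collapse = ", "))
  if (!nrow(keep)) return(keep[, c("line_id", "cv", "mean", "mode",
                                   "pct_germination"), drop = FALSE])
  rows <- lapply(split(keep, keep$line_id), function(d) {
    data.frame(line_id = d$line_id[1],
               cv = mean(d$cv), mean = mean(d$mean), mode = mean(d$mode),
               pct_germination = mean(d$pct_germination),
               n_plates = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank correlation between two line-level traits
#'
#' Spearman rank correlation across lines, with pairwise exclusion of
#' lines missing either trait.
#'
#' @param line_summaries data frame as from [aggregate_line()].
#' @param trait_x,trait_y column names (e.g. "cv", "mode").
#' @return list with `rho` and `n` (lines used).
#' @export
trait_correlation <- function(line_summaries, trait_x, trait_y) {
  x <- line_summaries[[trait_x]]
  y <- line_summaries[[trait_y]]
  if (is.null(x) || is.null(y)) stop("unknown trait column")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 lines with both traits")
  list(rho = stats::cor(x[ok], y[ok], method = "spearman"), n = sum(ok))
}
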