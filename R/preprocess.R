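# Trial-level preprocessing: reading, respondent exclusion, latency filtering,
# aggregation to the respondent x condition x stimulus matrix, and tertile
# discretization into ordinal speed categories.

.trial_cols <- c("respondent_id", "group", "block", "block_role", "condition",
                 "stimulus_id", "stimulus_class", "latency_ms", "error")

.attribute_classes <- c("attribute_positive", "attribute_negative")

#' Read trial-level IAT data
#'
#' Reads a delimited text file with one row per IAT trial. The file must have
#' a header with the columns `respondent_id`, `group`, `block`, `block_role`,
#' `condition`, `stimulus_id`, `stimulus_class`, `latency_ms` and `error`.
#' `block_role` is `"practice"` or `"critical"`; `condition` identifies the
#' associative response mapping of a critical block (e.g. `"HEG_HOB"` =
#' Heterosexuals-Good/Homosexuals-Bad) and is empty for practice blocks.
#'
#' Rows with an unparseable latency, block or error flag are rejected (not
#' fatal): they are counted, reported via [message()], and returned in the
#' `"rejections"` attribute of the result.
#'
#' @param path Path to a comma- or tab-delimited UTF-8 text file.
#' @param delim `"auto"` (default; detected from the header line), `"comma"`
#'   or `"tab"`.
#' @return A `data.frame` of trials with typed columns (`latency_ms` numeric,
#'   `block` integer, `error` logical, `condition` `NA` for practice rows) and
#'   an attribute `"rejections"`: a `data.frame` with `row` (file row number,
#'   header excluded) and `reason`.
#' @export
read_trials <- function(path, delim = c("auto", "comma", "tab")) {
  delim <- match.arg(delim)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- switch(delim,
    comma = ",",
    tab = "\t",
    auto = {
      n_tab <- nchar(header) - nchar(gsub("\t", "", header, fixed = TRUE))
      n_com <- nchar(header) - nchar(gsub(",", "", header, fixed = TRUE))
      if (n_tab > n_com) "\t" else ","
    }
  )
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character",
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  miss <- setdiff(.trial_cols, names(raw))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lat <- suppressWarnings(as.numeric(raw$latency_ms))
  blk <- suppressWarnings(as.integer(raw$block))
  err <- .parse_flag(raw$error)
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(err)] <- "unparseable error flag"
  reason[is.na(blk)] <- "unparseable block"
  reason[is.na(lat) | lat <= 0] <- "unparseable or non-positive latency"
  bad <- !is.na(reason)
  trials <- data.frame(
    respondent_id = raw$respondent_id,
    group = raw$group,
    block = blk,
    block_role = raw$block_role,
    condition = raw$condition,
    stimulus_id = raw$stimulus_id,
    stimulus_class = raw$stimulus_class,
    latency_ms = lat,
    error = err,
    stringsAsFactors = FALSE
  )[!bad, , drop = FALSE]
  rownames(trials) <- NULL
  rejections <- data.frame(row = which(bad), reason = reason[bad],
                           stringsAsFactors = FALSE)
  if (nrow(rejections) > 0) {
    message(nrow(rejections), " row(s) rejected while reading ", path)
  }
  attr(trials, "rejections") <- rejections
  trials
}

.parse_flag <- function(x) {
  out <- rep(NA, length(x))
  lx <- tolower(trimws(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Filter trials by latency range
#'
#' Removes trials with latencies below `min_ms` or above `max_ms`. The
#' boundaries are retained: only latencies strictly smaller than 300 ms or
#' strictly greater than 10,000 ms are excluded under the defaults.
#'
#' @param trials Trial `data.frame` as returned by [read_trials()].
#' @param min_ms,max_ms Inclusive latency bounds in milliseconds.
#' @return The retained trials, with an attribute `"n_removed"`: a named
#'   integer vector of removals per respondent (respondents with none removed
#'   are absent).
#' @export
filter_trials <- function(trials, min_ms = 300, max_ms = 10000) {
  keep <- trials$latency_ms >= min_ms & trials$latency_ms <= max_ms
  removed <- trials$respondent_id[!keep]
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- NULL
  n_removed <- integer(0)
  if (length(removed) > 0) {
    tab <- table(removed)
    n_removed <- stats::setNames(as.integer(tab), names(tab))
  }
  attr(out, "n_removed") <- n_removed
  if (nrow(out) == 0 && nrow(trials) > 0) {
    warning("all trials outside the latency range [", min_ms, ", ", max_ms,
            "] ms", call. = FALSE)
  }
  out
}

#' Respondent-level exclusion criteria
#'
#' The data-reduction criteria applied to internet IAT sessions before
#' modelling. Each criterion can be disabled (`FALSE`/`NA`).
#'
#' @param require_all_critical_blocks Exclude respondents missing any critical
#'   block present in the dataset.
#' @param max_fast_fraction Exclude respondents whose fraction of
#'   critical-block latencies below `fast_ms` exceeds this value.
#' @param fast_ms Threshold (ms) defining an anticipatory "fast" response.
#' @param max_error_rate Exclude respondents whose critical-block error rate
#'   exceeds this value.
#' @return A list of class `"exclusion_criteria"`.
#' @export
exclusion_criteria <- function(require_all_critical_blocks = TRUE,
                               max_fast_fraction = 0.10,
                               fast_ms = 300,
                               max_error_rate = 0.30) {
  structure(list(require_all_critical_blocks = isTRUE(require_all_critical_blocks),
                 max_fast_fraction = max_fast_fraction,
                 fast_ms = fast_ms,
                 max_error_rate = max_error_rate),
            class = "exclusion_criteria")
}

#' Apply respondent-level exclusions
#'
#' Removes, wholesale, every respondent violating any enabled criterion in
#' `criteria`. Criteria are evaluated on the unfiltered critical-block trials
#' (the fast-response criterion needs the sub-300 ms latencies that
#' [filter_trials()] would remove), so this step precedes latency filtering
#' in the pipeline.
#'
#' @param trials Trial `data.frame`.
#' @param criteria An [exclusion_criteria()] object.
#' @return A list with `trials` (retained rows, all blocks) and `report`, a
#'   `data.frame` with one row per excluded respondent and the triggering
#'   criterion (a respondent violating several is listed once per criterion).
#' @export
apply_respondent_exclusions <- function(trials,
                                        criteria = exclusion_criteria()) {
  stopifnot(inherits(criteria, "exclusion_criteria"))
  crit <- trials[trials$block_role == "critical", , drop = FALSE]
  report <- data.frame(respondent_id = character(0), criterion = character(0),
                       stringsAsFactors = FALSE)
  if (nrow(crit) > 0) {
    ids <- unique(trials$respondent_id)
    all_blocks <- sort(unique(crit$block))
    for (id in ids) {
      ci <- crit[crit$respondent_id == id, , drop = FALSE]
      if (criteria$require_all_critical_blocks &&
          !all(all_blocks %in% ci$block)) {
        report <- rbind(report, data.frame(respondent_id = id,
                                           criterion = "missing_critical_block"))
      }
      if (nrow(ci) > 0 && !is.na(criteria$max_fast_fraction) &&
          mean(ci$latency_ms < criteria$fast_ms) > criteria$max_fast_fraction) {
        report <- rbind(report, data.frame(respondent_id = id,
                                           criterion = "fast_fraction"))
      }
      if (nrow(ci) > 0 && !is.na(criteria$max_error_rate) &&
          mean(ci$error) > criteria$max_error_rate) {
        report <- rbind(report, data.frame(respondent_id = id,
                                           criterion = "error_rate"))
      }
    }
  }
  keep <- !(trials$respondent_id %in% report$respondent_id)
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- NULL
  list(trials = out, report = report)
}

#' Aggregate critical-block trials into the cell matrix
#'
#' Builds the respondent x associative-condition x attribute-stimulus matrix:
#' one cell per combination, holding the arithmetic mean latency and the
#' number of contributing trials. Target-stimulus and practice trials are
#' dropped; the grid is completed so that combinations with no trials appear
#' as missing cells (`n_trials = 0`, `mean_latency_ms = NA`), never as zeros.
#'
#' @param trials Filtered trial `data.frame`.
#' @param include_error_trials Keep error trials (with their recorded
#'   latencies) in the cell means. Default `TRUE`.
#' @return A `data.frame` with columns `respondent_id`, `group`, `condition`,
#'   `stimulus_id`, `stimulus_class`, `mean_latency_ms`, `n_trials` and
#'   `category` (all `NA` until [discretize_cells()]).
#' @export
aggregate_cells <- function(trials, include_error_trials = TRUE) {
  crit <- trials[trials$block_role == "critical" &
                   trials$stimulus_class %in% .attribute_classes, ,
                 drop = FALSE]
  if (!include_error_trials) {
    crit <- crit[!crit$error, , drop = FALSE]
  }
  if (nrow(crit) == 0) {
    stop("no critical-block attribute trials to aggregate", call. = FALSE)
  }
  resp <- unique(crit[, c("respondent_id", "group")])
  if (anyDuplicated(resp$respondent_id)) {
    stop("respondent(s) with more than one group label", call. = FALSE)
  }
  conds <- sort(unique(crit$condition))
  stim <- unique(crit[, c("stimulus_id", "stimulus_class")])
  stim <- stim[order(stim$stimulus_id), , drop = FALSE]
  grid <- expand.grid(stimulus_id = stim$stimulus_id, condition = conds,
                      respondent_id = resp$respondent_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("respondent_id", "condition", "stimulus_id")]
  grid$group <- resp$group[match(grid$respondent_id, resp$respondent_id)]
  grid$stimulus_class <- stim$stimulus_class[match(grid$stimulus_id,
                                                   stim$stimulus_id)]
  key_t <- paste(crit$respondent_id, crit$condition, crit$stimulus_id,
                 sep = "\r")
  key_g <- paste(grid$respondent_id, grid$condition, grid$stimulus_id,
                 sep = "\r")
  sums <- rowsum(crit$latency_ms, key_t)
  counts <- rowsum(rep(1L, nrow(crit)), key_t)
  m <- match(key_g, rownames(sums))
  grid$n_trials <- ifelse(is.na(m), 0L, counts[m, 1])
  grid$mean_latency_ms <- ifelse(is.na(m), NA_real_, sums[m, 1] / counts[m, 1])
  grid$category <- NA_integer_
  grid <- grid[, c("respondent_id", "group", "condition", "stimulus_id",
                   "stimulus_class", "mean_latency_ms", "n_trials",
                   "category")]
  rownames(grid) <- NULL
  grid
}

#' Global tertile cut points of the cell matrix
#'
#' Computes the empirical 1/3 and 2/3 quantiles of all non-missing cell mean
#' latencies, pooled over every respondent, condition and stimulus. The
#' linear-interpolation quantile definition is used (for probability `p` and
#' sorted values `v_1..v_N`, index `h = (N-1)p + 1`, value
#' `v_floor(h) + (h - floor(h)) (v_floor(h)+1 - v_floor(h))`; type 7 in
#' [stats::quantile()]).
#'
#' @param cells Cell matrix from [aggregate_cells()].
#' @return A list of class `"tertile_cuts"` with `lower_cut_ms` and
#'   `upper_cut_ms`.
#' @export
compute_tertiles <- function(cells) {
  x <- cells$mean_latency_ms
  x <- x[!is.na(x)]
  if (length(x) < 3) {
    stop("need at least 3 non-missing cells to compute tertiles",
         call. = FALSE)
  }
  q <- stats::quantile(x, probs = c(1, 2) / 3, type = 7, names = FALSE)
  structure(list(lower_cut_ms = q[1], upper_cut_ms = q[2]),
            class = "tertile_cuts")
}

#' @export
print.tertile_cuts <- function(x, ...) {
  cat(sprintf("Tertile cuts: %.1f ms / %.1f ms\n",
              x$lower_cut_ms, x$upper_cut_ms))
  invisible(x)
}

#' Discretize cell mean latencies into speed categories
#'
#' Maps each non-missing cell mean latency to an ordinal speed category:
#' 3 = fast (`mean <= lower_cut`), 2 = medium (`lower_cut < mean <=
#' upper_cut`), 1 = slow (`mean > upper_cut`). A mean lying exactly on a cut
#' goes to the faster (higher) category. Missing cells stay missing.
#'
#' @param cells Cell matrix from [aggregate_cells()].
#' @param cuts A `"tertile_cuts"` object from [compute_tertiles()].
#' @return `cells` with the `category` column filled in.
#' @export
discretize_cells <- function(cells, cuts) {
  stopifnot(inherits(cuts, "tertile_cuts"))
  m <- cells$mean_latency_ms
  cat <- ifelse(m <= cuts$lower_cut_ms, 3L,
                ifelse(m <= cuts$upper_cut_ms, 2L, 1L))
  cat[is.na(m)] <- NA_integer_
  cells$category <- cat
  cells
}

#' Run the full preprocessing pipeline
#'
#' Applies, in this fixed order: respondent-level exclusions (on unfiltered
#' trials), latency-range filtering, aggregation to the cell matrix, global
#' tertile computation, and discretization.
#'
#' @param trials Trial `data.frame` from [read_trials()] or
#'   [simulate_latencies()].
#' @param criteria [exclusion_criteria()] object.
#' @param include_error_trials Passed to [aggregate_cells()].
#' @param min_ms,max_ms Passed to [filter_trials()].
#' @return A list with `cells` (categorized cell matrix), `cuts`,
#'   `exclusions` (report `data.frame`) and `n_filtered` (trials removed by
#'   the latency filter, per respondent).
#' @export
preprocess_trials <- function(trials, criteria = exclusion_criteria(),
                              include_error_trials = TRUE,
                              min_ms = 300, max_ms = 10000) {
  ex <- apply_respondent_exclusions(trials, criteria)
  kept <- filter_trials(ex$trials, min_ms = min_ms, max_ms = max_ms)
  cells <- aggregate_cells(kept, include_error_trials = include_error_trials)
  cuts <- compute_tertiles(cells)
  cells <- discretize_cells(cells, cuts)
  list(cells = cells, cuts = cuts, exclusions = ex$report,
       n_filtered = attr(kept, "n_removed"))
}
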