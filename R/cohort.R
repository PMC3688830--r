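# Cohort container: a data.frame with one row per patient, class
# "sresc_cohort", and a "provenance" attribute
# ("reconstruction" | "file" | "simulated").

.hydro_levels <- c("normal", "mild", "moderate", "severe")
.clavien_levels <- c("none", "I", "II", "IIIA", "IIIB", "IVA", "IVB", "V")

.mandatory_cols <- c("patient_id", "sresc_score", "sresc_group", "stone_free")
.optional_cols <- c("sites", "age", "sex", "bmi", "laterality", "stone_count",
                    "largest_diameter_mm", "total_volume_cm3", "mean_hu",
                    "renometry", "hydronephrosis", "clavien_grade")

#' Construct and validate a patient cohort
#'
#' A cohort is a data frame with one row per patient carrying at minimum
#' `patient_id`, `sresc_score` (1-9), `sresc_group` and `stone_free` (0/1,
#' stone free on 1-month imaging).  Optional columns: `sites`
#' (semicolon-separated involved site ids), `age`, `sex` (`M`/`F`), `bmi`,
#' `laterality` (`L`/`R`), `stone_count`, `largest_diameter_mm`,
#' `total_volume_cm3`, `mean_hu`, `renometry`, `hydronephrosis`
#' (normal/mild/moderate/severe), `clavien_grade` (none/I/II/IIIA/IIIB/
#' IVA/IVB/V).  A missing score is computed from `sites` when present;
#' a missing group is derived from the score, and a stated group must be
#' consistent with it.
#'
#' @param data A data frame of patient rows.
#' @param provenance One of `"reconstruction"`, `"file"`, `"simulated"`.
#' @param strict If `TRUE`, columns outside the documented schema are an
#'   error; otherwise they are carried through untouched.
#' @return The validated data frame, class `"sresc_cohort"`.
#' @export
sresc_cohort <- function(data, provenance = c("file", "reconstruction",
                                              "simulated"),
                         strict = FALSE) {
  provenance <- match.arg(provenance)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  known <- c(.mandatory_cols, .optional_cols)
  extra <- setdiff(names(data), known)
  if (strict && length(extra))
    stop("unknown columns: ", paste(extra, collapse = ", "), call. = FALSE)
  if (nrow(data) == 0L) stop("cohort has no rows", call. = FALSE)

  if (is.null(data$patient_id))
    stop("missing mandatory column: patient_id", call. = FALSE)
  data$patient_id <- as.character(data$patient_id)
  dup <- duplicated(data$patient_id)
  if (any(dup))
    stop("duplicate patient_id: ",
         paste(unique(data$patient_id[dup]), collapse = ", "), call. = FALSE)

  # score: fill from sites where absent
  if (is.null(data$sresc_score)) data$sresc_score <- NA_integer_
  data$sresc_score <- suppressWarnings(as.integer(data$sresc_score))
  if (!is.null(data$sites)) {
    data$sites <- as.character(data$sites)
    need <- which(is.na(data$sresc_score) & !is.na(data$sites) &
                    nzchar(data$sites))
    for (i in need)
      data$sresc_score[i] <- sresc_score(data$sites[i])$score
  }
  bad <- which(is.na(data$sresc_score) | data$sresc_score < 1L |
                 data$sresc_score > 9L)
  if (length(bad))
    stop("sresc_score missing or outside 1-9 at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  grp <- score_group(data$sresc_score)
  if (!is.null(data$sresc_group)) {
    stated <- as.character(data$sresc_group)
    chk <- which(!is.na(stated) & nzchar(stated) & stated != grp)
    if (length(chk))
      stop("sresc_group inconsistent with sresc_score at row(s): ",
           paste(chk, collapse = ", "), call. = FALSE)
  }
  data$sresc_group <- factor(grp, levels = group_levels())

  if (is.null(data$stone_free))
    stop("missing mandatory column: stone_free", call. = FALSE)
  sf <- suppressWarnings(as.integer(data$stone_free))
  bad <- which(is.na(sf) | !(sf %in% c(0L, 1L)))
  if (length(bad))
    stop("stone_free must be 0 or 1; bad row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  data$stone_free <- sf

  check_vocab <- function(col, levels) {
    if (is.null(data[[col]])) return()
    v <- as.character(data[[col]])
    bad <- which(!is.na(v) & nzchar(v) & !(v %in% levels))
    if (length(bad))
      stop(col, " outside vocabulary {", paste(levels, collapse = ", "),
           "} at row(s): ", paste(bad, collapse = ", "), call. = FALSE)
    data[[col]] <<- factor(v, levels = levels)
  }
  check_vocab("hydronephrosis", .hydro_levels)
  check_vocab("clavien_grade", .clavien_levels)
  check_vocab("renometry", renometry_levels())

  rownames(data) <- NULL
  structure(data, provenance = provenance,
            class = c("sresc_cohort", "data.frame"))
}

#' Cohort provenance label
#' @param cohort An `sresc_cohort`.
#' @return `"reconstruction"`, `"file"` or `"simulated"`.
#' @export
provenance <- function(cohort) attr(cohort, "provenance")

#' @export
print.sresc_cohort <- function(x, ...) {
  cat(sprintf("S-ReSC cohort: %d patients (provenance: %s)\n",
              nrow(x), provenance(x)))
  cat(sprintf("  stone free: %d (%.1f%%)\n", sum(x$stone_free),
              100 * mean(x$stone_free)))
  NextMethod()
}

# Per-score (stone-free, failure) counts of the 155-patient development
# cohort, read off the published stone-free fractions 40/42, 32/33, 19/26,
# 10/16, 5/15, 3/9, 2/5, 0/6, 1/3 for scores 1..9.
.dev_counts <- data.frame(
  score      = 1:9,
  stone_free = c(40L, 32L, 19L, 10L, 5L, 3L, 2L, 0L, 1L),
  failure    = c(2L, 1L, 7L, 6L, 10L, 6L, 3L, 6L, 2L))

#' Reconstruct the 155-patient development cohort
#'
#' Rebuilds, exactly and deterministically, the single-centre development
#' cohort of 155 consecutive sPCNL cases from its published per-score
#' stone-free fractions (40/42, 32/33, 19/26, 10/16, 5/15, 3/9, 2/5, 0/6,
#' 1/3 for scores 1-9).  The joint distribution of (score, outcome) is
#' fully determined by those counts, so every score-outcome analysis on
#' this cohort is an exact reproduction.  Records carry only
#' `patient_id`, `sresc_score`, `sresc_group` and `stone_free`: the
#' per-patient covariates and stone maps of the original series are not
#' public, and no column here should be mistaken for them.
#'
#' @return An `sresc_cohort` of 155 records, provenance
#'   `"reconstruction"`, ordered by score with stone-free cases first.
#' @examples
#' co <- reconstructed_cohort()
#' nrow(co)              # 155
#' sum(co$stone_free)    # 112
#' @export
reconstructed_cohort <- function() {
  cnt <- .dev_counts
  score <- rep(rep(cnt$score, 2L), c(cnt$stone_free, cnt$failure))
  sf <- rep(rep(c(1L, 0L), each = 9L), c(cnt$stone_free, cnt$failure))
  o <- order(score, -sf)
  d <- data.frame(patient_id = sprintf("P%03d", seq_along(score)),
                  sresc_score = score[o],
                  sresc_group = score_group(score[o]),
                  stone_free = sf[o],
                  stringsAsFactors = FALSE)
  sresc_cohort(d, provenance = "reconstruction")
}

#' Read a cohort from CSV
#'
#' Expects the documented cohort dialect: UTF-8, comma separated, header
#' row, empty fields for missing values.  Rows with `sites` but no
#' `sresc_score` get the score computed from the sites.  Validation errors
#' name the offending rows.
#'
#' @param path CSV file path.
#' @param strict Reject columns outside the documented schema.
#' @return An `sresc_cohort` with provenance `"file"`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, strict = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", na.strings = "")
  missing <- setdiff(setdiff(.mandatory_cols, "sresc_group"), names(d))
  missing <- setdiff(missing, if ("sites" %in% names(d)) "sresc_score")
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in intersect(c("sresc_score", "stone_free", "age", "bmi",
                          "stone_count", "largest_diameter_mm",
                          "total_volume_cm3", "mean_hu"), names(d)))
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  sresc_cohort(d, provenance = "file", strict = strict)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writing then reading reproduces all fields.
#'
#' @param cohort An `sresc_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "sresc_cohort"))
  d <- as.data.frame(cohort)
  for (col in names(d)) if (is.factor(d[[col]])) d[[col]] <- as.character(d[[col]])
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarise a cohort
#'
#' @param cohort An `sresc_cohort`.
#' @return An object of class `"sresc_summary"`: `n`, `mean_score`,
#'   `sd_score` (sample SD, n-1 denominator; 0 with a warning for a single
#'   record), `sfr_overall`, and data frames `by_score` and `by_group`
#'   with columns `n`, `stone_free`, `sfr`.
#' @examples
#' cohort_summary(reconstructed_cohort())
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "sresc_cohort"))
  n <- nrow(cohort)
  sd_score <- if (n == 1L) {
    warning("single-record cohort: score SD reported as 0", call. = FALSE)
    0
  } else stats::sd(cohort$sresc_score)
  by_tab <- function(f) {
    nn <- as.integer(table(f))
    sf <- as.integer(tapply(cohort$stone_free, f, sum, default = 0L))
    data.frame(n = nn, stone_free = sf,
               sfr = ifelse(nn > 0, sf / nn, NA_real_))
  }
  sc <- factor(cohort$sresc_score, levels = 1:9)
  by_score <- cbind(score = 1:9, by_tab(sc))
  by_group <- cbind(group = group_levels(), by_tab(cohort$sresc_group))
  structure(list(n = n,
                 mean_score = mean(cohort$sresc_score),
                 sd_score = sd_score,
                 sfr_overall = mean(cohort$stone_free),
                 by_score = by_score,
                 by_group = by_group),
            class = "sresc_summary")
}

#' @export
print.sresc_summary <- function(x, ...) {
  cat(sprintf("n = %d patients; S-ReSC score %.2f +/- %.2f\n",
              x$n, x$mean_score, x$sd_score))
  cat(sprintf("overall stone-free rate: %.1f%%\n", 100 * x$sfr_overall))
  cat("\nStone-free rate by score group:\n")
  g <- x$by_group
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-7s %5.1f%% (%d/%d)\n", g$group[i], 100 * g$sfr[i],
                g$stone_free[i], g$n[i]))
  invisible(x)
}
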