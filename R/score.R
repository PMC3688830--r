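#' sresc: renal stone complexity scoring and stone-free outcome prediction
#'
#' The S-ReSC (Seoul National University Renal Stone Complexity) score counts
#' the number of pelvicalyceal sites involved by stone, out of nine
#' pre-determined locations, regardless of stone size or number.  A higher
#' count means a more complex stone distribution and a lower probability of
#' being stone free after single-tract percutaneous nephrolithotomy (sPCNL).
#'
#' The package covers the full validation workflow for such a score:
#' deterministic scoring and grouping ([sresc_score()], [score_group()]),
#' cohort handling and the exact reconstruction of the 155-patient
#' development cohort ([reconstructed_cohort()]), logistic regression with
#' Wald inference ([fit_logistic()]), tie-corrected AUC ([auc_with_ties()]),
#' quadratic-weighted kappa ([weighted_kappa()]), bootstrap
#' optimism-corrected calibration ([calibration_bootstrap()]), decision
#' curve analysis ([decision_curve()]), and a seeded synthetic cohort
#' generator ([simulate_cohort()]).
#'
#' @keywords internal
"_PACKAGE"

# The nine scoring sites.  Site ids are fixed:
#   1       renal pelvis
#   2, 3    superior / inferior major calyceal group (major calyx + infundibulum)
#   4, 5    anterior / posterior minor calyceal group of the superior calyx
#   6, 7    anterior / posterior minor calyceal group of the middle calyx
#   8, 9    anterior / posterior minor calyceal group of the inferior calyx

#' Names of the nine pelvicalyceal scoring sites
#'
#' @return A named character vector of length 9; names are the site ids
#'   `"1"`-`"9"`.
#' @examples
#' site_labels()[["1"]]
#' @export
site_labels <- function() {
  c(`1` = "renal pelvis",
    `2` = "superior major calyceal group",
    `3` = "inferior major calyceal group",
    `4` = "anterior minor calyceal group, superior calyx",
    `5` = "posterior minor calyceal group, superior calyx",
    `6` = "anterior minor calyceal group, middle calyx",
    `7` = "posterior minor calyceal group, middle calyx",
    `8` = "anterior minor calyceal group, inferior calyx",
    `9` = "posterior minor calyceal group, inferior calyx")
}

# Calyceal regions used by the staghorn classification.  A region is
# involved when any of its sites is involved; the major calyx and the minor
# calyces draining into it belong to the same region.
.calyceal_regions <- list(superior = c(2L, 4L, 5L),
                          middle   = c(6L, 7L),
                          inferior = c(3L, 8L, 9L))

# Validate, deduplicate and sort a vector of site ids.  allow_empty = TRUE
# is used by the rater simulator, where a perturbed map may transiently be
# empty; scoring itself always rejects empty maps.
validate_sites <- function(sites, allow_empty = FALSE) {
  if (is.character(sites) && length(sites) == 1L) {
    sites <- strsplit(sites, "[;,]")[[1]]
    sites <- sites[nzchar(trimws(sites))]
  }
  if (length(sites) == 0L) {
    if (allow_empty) return(integer(0))
    stop("empty stone map: no stone to score", call. = FALSE)
  }
  s <- suppressWarnings(as.numeric(sites))
  if (anyNA(s) || any(s != floor(s)))
    stop("site ids must be integers 1-9, got: ",
         paste(sites, collapse = ", "), call. = FALSE)
  if (any(s < 1 | s > 9))
    stop("site ids out of range 1-9: ",
         paste(s[s < 1 | s > 9], collapse = ", "), call. = FALSE)
  sort(unique(as.integer(s)))
}

#' Compute the S-ReSC score of a stone map
#'
#' The score is the number of distinct involved sites among the nine
#' pelvicalyceal locations; one point per site, maximum 9.  Duplicate site
#' entries count once and listing order is irrelevant.
#'
#' @param sites Involved site ids: an integer vector with values in 1-9, or
#'   a single string such as `"1;2;4;5"` (`;` or `,` separated).
#' @return An object of class `"sresc_score"`: a list with elements
#'   `score` (integer 1-9), `group` (`"low"`, `"medium"` or `"high"`), and
#'   `sites` (the sorted involved site ids).
#' @examples
#' sresc_score(c(1, 2, 4, 5))   # score 4, medium
#' sresc_score("1;2;4;5")
#' @seealso [score_group()], [classify_renometry()]
#' @export
sresc_score <- function(sites) {
  sites <- validate_sites(sites)
  score <- length(sites)
  structure(list(score = score, group = score_group(score), sites = sites),
            class = "sresc_score")
}

#' @export
print.sresc_score <- function(x, ...) {
  cat("S-ReSC score:", x$score, sprintf("(%s group)\n", x$group))
  cat("Involved sites:", paste(x$sites, collapse = ", "), "\n")
  invisible(x)
}

#' Map an S-ReSC score to its 3-tier risk group
#'
#' Scores 1-2 are `low`, 3-4 `medium`, 5-9 `high`.  Vectorised.
#'
#' @param score Integer score(s) in 1-9.
#' @return Character vector of group labels.
#' @examples
#' score_group(1:9)
#' @export
score_group <- function(score) {
  if (length(score) == 0L) return(character(0))
  s <- suppressWarnings(as.numeric(score))
  if (anyNA(s) || any(s != floor(s)) || any(s < 1 | s > 9))
    stop("score must be an integer in 1-9", call. = FALSE)
  c("low", "low", "medium", "medium",
    "high", "high", "high", "high", "high")[as.integer(s)]
}

#' Ordered group levels of the 3-tier S-ReSC grouping
#' @return `c("low", "medium", "high")`
#' @export
group_levels <- function() c("low", "medium", "high")

#' Classify a stone map into a renometry category
#'
#' A complete staghorn is a renal pelvic stone extending into all major
#' calyceal groups and filling at least 80% of the collecting system; a
#' partial staghorn is a pelvic stone extending into at least two calyceal
#' groups.  Calyceal groups on the 9-site grid are superior = sites
#' \{2, 4, 5\}, middle = \{6, 7\}, inferior = \{3, 8, 9\}; a group is
#' involved when any of its sites is.  The remaining categories follow the
#' pelvis flag and the count of involved calyceal sites.
#'
#' @param sites Involved site ids (as for [sresc_score()]).
#' @param fill_fraction Radiologically estimated fraction (0-1) of the
#'   collecting system filled by stone.  Supplied by the reader, not
#'   derived from geometry.
#' @return One of `"complete staghorn"`, `"partial staghorn"`,
#'   `"pelvis+multiple calyces"`, `"pelvis+single calyx"`, `"pelvis only"`,
#'   `"multiple calyces"`, `"single calyx"`.
#' @examples
#' classify_renometry(c(1, 2, 3, 4, 6, 8), fill_fraction = 0.85)
#' classify_renometry(c(1, 2, 8), fill_fraction = 0.3)
#' classify_renometry(1)
#' @export
classify_renometry <- function(sites, fill_fraction = 0) {
  sites <- validate_sites(sites)
  if (!is.numeric(fill_fraction) || length(fill_fraction) != 1L ||
      is.na(fill_fraction) || fill_fraction < 0 || fill_fraction > 1)
    stop("fill_fraction must be a single number in [0, 1]", call. = FALSE)
  pelvis <- 1L %in% sites
  calyceal <- setdiff(sites, 1L)
  n_regions <- sum(vapply(.calyceal_regions,
                          function(r) any(r %in% calyceal), logical(1)))
  if (pelvis && n_regions == 3L && fill_fraction >= 0.8)
    return("complete staghorn")
  if (pelvis && n_regions >= 2L) return("partial staghorn")
  if (pelvis && length(calyceal) >= 2L) return("pelvis+multiple calyces")
  if (pelvis && length(calyceal) == 1L) return("pelvis+single calyx")
  if (pelvis) return("pelvis only")
  if (length(calyceal) >= 2L) return("multiple calyces")
  "single calyx"
}

#' Renometry category labels
#' @return Character vector of the seven category labels.
#' @export
renometry_levels <- function() {
  c("complete staghorn", "partial staghorn", "pelvis+multiple calyces",
    "pelvis+single calyx", "pelvis only", "multiple calyces", "single calyx")
}

#' Estimated stone volume from CT calliper measurements
#'
#' Volume is computed as length x width x depth x pi x 0.52, the formula
#' used when the development cohort was assembled.  Note that this exceeds
#' the standard scalene-ellipsoid estimate (length x width x depth x 0.52,
#' i.e. pi/6 per dimension product) by a factor of pi; it is kept as
#' published so that volumes are comparable with the original series.
#' Vectorised over stones.
#'
#' @param length_mm,width_mm,depth_mm Stone dimensions in mm (non-negative).
#' @return Volume(s) in cubic millimetres.
#' @examples
#' stone_volume(10, 10, 10)   # 1633.628
#' @export
stone_volume <- function(length_mm, width_mm, depth_mm) {
  d <- cbind(length_mm, width_mm, depth_mm)
  if (!is.numeric(d) || anyNA(d))
    stop("stone dimensions must be numeric and non-missing", call. = FALSE)
  if (any(d < 0))
    stop("stone dimensions must be non-negative", call. = FALSE)
  as.numeric(length_mm * width_mm * depth_mm * pi * 0.52)
}

#' Total stone volume of a kidney
#'
#' Sum of per-stone volumes; an empty set of stones has volume 0.
#'
#' @param stones A data frame (or matrix) with columns `length_mm`,
#'   `width_mm`, `depth_mm`, one row per stone.  May have zero rows.
#' @return Total volume in cubic millimetres.
#' @examples
#' total_stone_volume(data.frame(length_mm = c(10, 10), width_mm = 10,
#'                               depth_mm = 10))
#' @export
total_stone_volume <- function(stones) {
  stones <- as.data.frame(stones)
  if (nrow(stones) == 0L) return(0)
  need <- c("length_mm", "width_mm", "depth_mm")
  if (!all(need %in% names(stones)))
    stop("stones must have columns length_mm, width_mm, depth_mm",
         call. = FALSE)
  sum(stone_volume(stones$length_mm, stones$width_mm, stones$depth_mm))
}
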