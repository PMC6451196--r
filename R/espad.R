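#' Band lifetime occasion counts to the ESPAD 0-6 ordinal scale
#'
#' The European School Survey Project on Alcohol and Drugs (ESPAD) reports
#' lifetime substance-use occasions in seven ordered categories:
#' 0 (0 occasions), 1 (1-2), 2 (3-5), 3 (6-9), 4 (10-19), 5 (20-39),
#' 6 (40 or more).
#'
#' @param count vector of non-negative integer occasion counts.
#' @return integer vector of ESPAD categories in 0..6.
#' @examples
#' espad_band(c(0, 2, 5, 15, 40, 1000))
#' @export
espad_band <- function(count) {
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  findInterval(count, c(1, 3, 6, 10, 20, 40))
}

#' Assign onset-stratified drinking groups from three-wave ESPAD binge scores
#'
#' Subjects are stratified by the assessment wave (age 14, 16 or 19) at which
#' their banded lifetime-drunkenness score first reaches `onset_threshold`:
#' long-term drinkers crossed by age 14, medium-term first at 16, short-term
#' first at 19. Subjects with zero binge scores at all waves are controls and
#' are split deterministically (by subject-id order) into Control I and
#' Control II with the configured sizes. Subjects with non-zero but always
#' sub-threshold scores are flagged `excluded`.
#'
#' @param phenotypes data.frame with columns `subject_id`, `binge_14`,
#'   `binge_16`, `binge_19` (banded 0-6 scores).
#' @param onset_threshold banded binge score (0-6) defining a binge drinker at
#'   a wave; default 2 (three or more lifetime drunken episodes).
#' @param control_sizes length-2 numeric, target sizes for Control I and
#'   Control II. If they do not sum to the number of controls the split is
#'   proportional.
#' @return data.frame with columns `subject_id` and `group` (one of
#'   `long_term`, `medium_term`, `short_term`, `control_I`, `control_II`,
#'   `excluded`).
#' @export
assign_groups <- function(phenotypes, onset_threshold = 2,
                          control_sizes = c(control_I = 44, control_II = 21)) {
  waves <- c("binge_14", "binge_16", "binge_19")
  missing_cols <- setdiff(waves, names(phenotypes))
  if (length(missing_cols)) {
    stop("missing wave column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  b <- as.matrix(phenotypes[, waves])
  if (anyNA(b)) {
    bad <- waves[colSums(is.na(b)) > 0]
    stop("missing binge scores in wave(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(b < 0 | b > 6)) stop("banded scores must lie in [0, 6]", call. = FALSE)
  thr <- onset_threshold
  group <- rep("excluded", nrow(b))
  group[b[, 1] >= thr] <- "long_term"
  group[b[, 1] < thr & b[, 2] >= thr] <- "medium_term"
  group[b[, 1] < thr & b[, 2] < thr & b[, 3] >= thr] <- "short_term"
  is_control <- rowSums(b) == 0
  group[is_control] <- "control"

  ctrl_idx <- which(is_control)
  if (length(ctrl_idx)) {
    ord <- ctrl_idx[order(as.character(phenotypes$subject_id[ctrl_idx]))]
    n_ctrl <- length(ord)
    n1 <- if (sum(control_sizes) == n_ctrl) {
      control_sizes[[1]]
    } else {
      round(n_ctrl * control_sizes[[1]] / sum(control_sizes))
    }
    group[ord] <- rep(c("control_I", "control_II"), c(n1, n_ctrl - n1))
  }
  data.frame(subject_id = phenotypes$subject_id, group = group,
             stringsAsFactors = FALSE)
}

#' Split the cohort into training and held-out test samples
#'
#' The training sample pools Control I with the long- and short-term drinkers;
#' the independent test sample pools Control II with the medium-term drinkers.
#' Excluded subjects belong to neither.
#'
#' @param groups data.frame as returned by [assign_groups()].
#' @return the input with an added `sample` column in
#'   `{"train", "test", "excluded"}`.
#' @export
split_train_test <- function(groups) {
  train_groups <- c("control_I", "long_term", "short_term")
  test_groups <- c("control_II", "medium_term")
  empty <- setdiff(c(train_groups, test_groups), unique(groups$group))
  if (length(empty)) {
    warning("empty group(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  groups$sample <- ifelse(groups$group %in% train_groups, "train",
                          ifelse(groups$group %in% test_groups, "test",
                                 "excluded"))
  groups
}
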