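#' Read a scan manifest CSV
#'
#' The manifest has exactly the columns `scan_id`, `subject_id`,
#' `ga_at_scan_weeks`, `has_structural`, `has_multiecho`, `brain_in_fov`,
#' `motion_correctable`, `group`, `outcome`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of scan records.
#' @export
read_manifest <- function(path) {
  req <- c("scan_id", "subject_id", "ga_at_scan_weeks", "has_structural",
           "has_multiecho", "brain_in_fov", "motion_correctable", "group",
           "outcome")
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("has_structural", "has_multiecho", "brain_in_fov",
                "motion_correctable")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Apply the study inclusion filters to a scan manifest
#'
#' A scan is included iff it has both the structural and the multi-echo
#' sequence, gestational age at scan is at least 20 weeks, the brain lies
#' in the field of view, and its motion could be corrected. The exclusion
#' log records the *first* failing rule per excluded scan, with rules
#' evaluated in the fixed order sequences, gestational age, field of view,
#' motion -- so the log is deterministic.
#'
#' @param records Manifest data frame (see [read_manifest()]).
#' @return List with `included` (data frame) and `exclusions` (data frame
#'   with columns `scan_id`, `rule`).
#' @export
apply_inclusion_filters <- function(records) {
  if (nrow(records) == 0) {
    return(list(included = records,
                exclusions = data.frame(scan_id = character(0),
                                        rule = character(0))))
  }
  rule <- rep(NA_character_, nrow(records))
  fail_seq <- !(records$has_structural & records$has_multiecho)
  fail_ga <- records$ga_at_scan_weeks < 20
  fail_fov <- !records$brain_in_fov
  fail_mot <- !records$motion_correctable
  rule[is.na(rule) & fail_seq] <- "missing_sequences"
  rule[is.na(rule) & fail_ga] <- "ga_below_20_weeks"
  rule[is.na(rule) & fail_fov] <- "brain_not_in_fov"
  rule[is.na(rule) & fail_mot] <- "excessive_motion"
  keep <- is.na(rule)
  list(included = records[keep, , drop = FALSE],
       exclusions = data.frame(scan_id = records$scan_id[!keep],
                               rule = rule[!keep],
                               stringsAsFactors = FALSE))
}

#' Stratify included scans by group and outcome
#'
#' @param records Already-filtered manifest records.
#' @return List with `n_scans`, `n_subjects`, per-`group` scan and subject
#'   counts (`scans_by_group`, `subjects_by_group`) and per-`outcome` scan
#'   counts (`scans_by_outcome`).
#' @export
stratify <- function(records) {
  by_group_scans <- table(records$group)
  by_group_subj <- tapply(records$subject_id, records$group,
                          function(x) length(unique(x)))
  list(n_scans = nrow(records),
       n_subjects = length(unique(records$subject_id)),
       scans_by_group = as.list(by_group_scans),
       subjects_by_group = as.list(by_group_subj),
       scans_by_outcome = as.list(table(records$outcome)))
}

#' Path to the packaged study-population manifest
#'
#' A synthetic manifest of 193 scans from 145 individuals whose attributes
#' reproduce every box of the study-population flow chart: 150 scans (114
#' individuals) with both sequences, 8 scans excluded for gestational age
#' below 20 weeks, 1 for the brain outside the field of view, 6 for
#' uncorrectable motion, leaving 135 included scans from 107 individuals,
#' of which 92 scans (71 individuals) are controls and 43 scans (36
#' individuals) carry a pathology. Control gestational ages follow the
#' per-bin counts of the normative table.
#'
#' @return Path to the packaged CSV.
#' @export
study_manifest_path <- function() {
  system.file("extdata", "figure2_manifest.csv", package = "fetalt2star")
}

#' Generate the synthetic study-population manifest
#'
#' Deterministic generator of the manifest described in
#' [study_manifest_path()]; the packaged CSV is its output.
#'
#' @return Data frame in manifest format.
#' @export
simulate_cohort_manifest <- function() {
  ref <- reference_t2star_table()
  bins <- unique(ref[, c("bin_start", "n")])
  rows <- list()
  scan_i <- 0L
  add <- function(subject, ga, has_s = TRUE, has_m = TRUE, fov = TRUE,
                  mot = TRUE, group = "control", outcome = "control") {
    scan_i <<- scan_i + 1L
    rows[[scan_i]] <<- data.frame(
      scan_id = sprintf("SC%03d", scan_i), subject_id = subject,
      ga_at_scan_weeks = round(ga, 2), has_structural = has_s,
      has_multiecho = has_m, brain_in_fov = fov, motion_correctable = mot,
      group = group, outcome = outcome, stringsAsFactors = FALSE)
  }
  subj <- function(i) sprintf("S%03d", i)

  # 71 control subjects, 92 scans (21 subjects scanned twice); control GA
  # values spread deterministically within the normative bins at the
  # per-bin counts (8,10,11,9,9,8,11,8,7,11).
  control_ga <- unlist(lapply(seq_len(nrow(bins)), function(b) {
    n <- bins$n[b]
    bins$bin_start[b] + 2 * (seq_len(n) - 0.5) / n * 0.999
  }))
  ctrl_subject <- c(rep(seq_len(21), each = 2), 21 + seq_len(50))
  for (i in seq_along(control_ga)) {
    add(subj(ctrl_subject[i]), control_ga[i])
  }
  # 8 of these control subjects also had a scan excluded later:
  # 3 below 20 weeks, 5 with uncorrectable motion.
  for (i in 1:3) add(subj(i), 18 + 0.5 * i)
  for (i in 4:8) add(subj(i), 24 + i, mot = FALSE)

  # 36 pathology subjects (ids 72..107), 43 scans (7 scanned twice).
  pathologies <- c(rep("ventriculomegaly", 12),
                   rep("hypertension", 8),
                   rep("gestational_diabetes", 7),
                   rep("preterm_birth", 5),
                   rep("pre_eclampsia", 4),
                   rep("cytomegalovirus_infection", 2),
                   "agenesis_corpus_callosum", "trisomy_21",
                   rep("other", 3))
  path_subject <- 71 + c(rep(seq_len(7), each = 2), 7 + seq_len(29))
  path_ga <- 20.5 + (seq_len(43) - 1) * (19 / 42)
  for (i in seq_len(43)) {
    add(subj(path_subject[i]), path_ga[i], group = "pathology",
        outcome = pathologies[i])
  }

  # 7 subjects (ids 108..114) whose only scan was excluded after the
  # sequence check: 5 below 20 weeks, 1 brain outside FOV, 1 motion.
  for (i in 1:5) add(subj(107 + i), 17 + 0.4 * i)
  add(subj(113), 27, fov = FALSE)
  add(subj(114), 31, mot = FALSE)

  # 31 subjects (ids 115..145) lacking one of the two sequences:
  # 43 scans (12 subjects scanned twice), alternately missing the
  # structural or the multi-echo acquisition.
  seq_subject <- 114 + c(rep(seq_len(12), each = 2), 12 + seq_len(19))
  for (i in seq_len(43)) {
    if (i %% 2 == 0) {
      add(subj(seq_subject[i]), 22 + (i %% 17), has_s = FALSE)
    } else {
      add(subj(seq_subject[i]), 22 + (i %% 17), has_m = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
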