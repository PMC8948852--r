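# Participant/cohort records, persistence, and the end-to-end pipeline:
# simulation -> angle series -> AROM -> Fugl-Meyer scoring -> group reports.

.roman_levels <- c("I", "II", "III", "IV", "V")

#' Read a cohort table CSV
#'
#' Dialect: columns `id`, `group` (`control`/`study`), `chronological_age`,
#' `mental_age` (`-` or empty = absent), `macs`, `gmfcs` (roman I-V or
#' absent), `fma_total` (optional). A 36-child example cohort (18 control +
#' 18 study) ships with the package; see the example. GMFCS/MACS levels
#' beyond II trigger an eligibility warning (study inclusion requires level
#' I-II) but the row is kept.
#'
#' @param path File path; defaults to the bundled example cohort.
#' @return data.frame of class `cohort_table`.
#' @export
#' @examples
#' co <- read_cohort()
#' table(co$group)
read_cohort <- function(path = system.file("extdata", "cohort_children.csv",
                                           package = "kinarom")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "group", "chronological_age")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$id))
    stop("schema error: duplicate participant id: ",
         df$id[duplicated(df$id)][1], call. = FALSE)
  if (!all(df$group %in% c("control", "study")))
    stop("schema error: group must be 'control' or 'study'", call. = FALSE)
  absent <- function(v) is.na(v) | v %in% c("", "-", "NA")
  num <- function(v) ifelse(absent(v), NA_real_, suppressWarnings(as.numeric(v)))
  df$chronological_age <- num(df$chronological_age)
  if (any(is.na(df$chronological_age)) || any(df$chronological_age <= 0))
    stop("chronological_age must be a positive number for every row",
         call. = FALSE)
  if ("mental_age" %in% names(df)) df$mental_age <- num(df$mental_age)
  for (col in c("macs", "gmfcs")) {
    if (!col %in% names(df)) next
    v <- df[[col]]
    v[absent(v)] <- NA_character_
    bad <- which(!is.na(v) & !v %in% .roman_levels)
    if (length(bad))
      stop("schema error: invalid ", toupper(col), " level '", v[bad[1]],
           "' for id ", df$id[bad[1]], call. = FALSE)
    over <- which(!is.na(v) & !v %in% c("I", "II"))
    if (length(over))
      warning("eligibility: ", toupper(col), " level beyond II for id(s) ",
              paste(df$id[over], collapse = ", "),
              " (inclusion requires level I-II)", call. = FALSE)
    df[[col]] <- v
  }
  if ("fma_total" %in% names(df)) {
    df$fma_total <- num(df$fma_total)
    bad <- which(!is.na(df$fma_total) &
                   (df$fma_total < 0 | df$fma_total > 66))
    if (length(bad))
      stop("fma_total out of 0..66 for id ", df$id[bad[1]], call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

# Score one simulated participant record end to end.
.score_record <- function(rec, thresholds, bands, window) {
  aroms <- list()
  for (side in names(rec$streams)) {
    st <- rec$streams[[side]]
    aroms[[side]] <- list(
      abduction = extract_arom(
        angle_series(st$abduction, "shoulder_abduction", side),
        window = window),
      flexion = extract_arom(
        angle_series(st$flexion, "elbow_flexion", side), window = window),
      # extension AROM: the straightest (largest included) elbow angle seen;
      # taken from the dedicated extension stream when present, else from the
      # flexion session
      extension = extract_arom(
        angle_series(if (!is.null(st$extension)) st$extension else st$flexion,
                     "elbow_extension", side), window = window))
  }
  # automated items are scored on the worse (lower-AROM) side, the side the
  # assessment targets in hemiparesis
  worse <- names(aroms)[which.min(vapply(aroms, function(a) a$abduction$arom,
                                         numeric(1)))]
  auto <- list(
    shoulder_abduction = score_a2_item(aroms[[worse]]$abduction$arom,
                                       "shoulder_abduction", thresholds),
    elbow_flexion = score_a2_item(aroms[[worse]]$flexion$arom,
                                  "elbow_flexion", thresholds),
    elbow_extension = score_a2_item(aroms[[worse]]$extension$arom,
                                    "elbow_extension", thresholds))
  sheet <- assemble_sheet(rec$manual_sheet, auto,
                          participant = rec$id, side = worse)
  total <- total_score(sheet)
  list(id = rec$id, group = rec$group, aroms = aroms, tested_side = worse,
       sheet = sheet, fma_total = total,
       category = classify_capacity(total, bands))
}

#' Run the full assessment pipeline over a cohort
#'
#' Accepts either a list of simulated `participant_record`s (from
#' [simulate_cohort()]; streams are reduced to AROM, automated items scored,
#' sheets assembled and totals classified) or a [read_cohort()] table carrying
#' pre-assessed `fma_total` values (classification and group comparison only).
#' Records that fail (e.g. missing streams) become entries in `failures`; the
#' run continues. The pipeline itself draws no random numbers, so results are
#' fully determined by its inputs.
#'
#' @param cohort List of participant records, or a `cohort_table`.
#' @param thresholds Automated-item thresholds, see [a2_default_thresholds()].
#' @param bands Capacity bands, see [capacity_bands()].
#' @param window AROM smoothing window.
#' @param alpha Significance level of the group comparisons.
#' @return List of class `report_bundle`: `participants` (data.frame),
#'   `comparisons` (data.frame, control vs study rows), `shares` (per-group
#'   classification shares), `failures` (named list of error messages).
#' @export
run_pipeline <- function(cohort, thresholds = a2_default_thresholds(),
                         bands = capacity_bands("hybrid"), window = 5,
                         alpha = 0.05) {
  failures <- list()
  if (inherits(cohort, "cohort_table")) {
    if (!"fma_total" %in% names(cohort) || all(is.na(cohort$fma_total)))
      stop("cohort table carries no fma_total column to analyse", call. = FALSE)
    keep <- !is.na(cohort$fma_total)
    part <- data.frame(id = cohort$id[keep], group = cohort$group[keep],
                       fma_total = cohort$fma_total[keep],
                       category = vapply(cohort$fma_total[keep],
                                         classify_capacity, character(1),
                                         bands = bands),
                       stringsAsFactors = FALSE)
    comparisons <- NULL
    if (all(c("control", "study") %in% part$group))
      comparisons <- compare_groups(
        part$fma_total[part$group == "control"],
        part$fma_total[part$group == "study"],
        label = "fma_total", alpha = alpha, decimals = 0,
        method = "normal_approx")
  } else {
    scored <- list()
    for (rec in cohort) {
      res <- tryCatch(.score_record(rec, thresholds, bands, window),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures[[rec$id]] <- conditionMessage(res)
      } else scored[[res$id]] <- res
    }
    if (length(scored) == 0L)
      stop("no record could be scored; first failure: ",
           if (length(failures)) failures[[1]] else "none", call. = FALSE)
    part <- do.call(rbind, lapply(scored, function(s) {
      mean_sides <- function(mv)
        mean(vapply(s$aroms, function(a) a[[mv]]$arom, numeric(1)))
      data.frame(id = s$id, group = s$group,
                 abduction_arom = mean_sides("abduction"),
                 flexion_arom = mean_sides("flexion"),
                 tested_side = s$tested_side,
                 fma_total = s$fma_total, category = s$category,
                 stringsAsFactors = FALSE)
    }))
    rownames(part) <- NULL
    comparisons <- NULL
    if (all(c("control", "study") %in% part$group)) {
      cg <- part[part$group == "control", ]; sg <- part[part$group == "study", ]
      comparisons <- rbind(
        compare_groups(cg$abduction_arom, sg$abduction_arom,
                       "shoulder_abduction_arom", alpha = alpha),
        compare_groups(cg$flexion_arom, sg$flexion_arom,
                       "elbow_flexion_arom", alpha = alpha),
        compare_groups(cg$fma_total, sg$fma_total, "fma_total",
                       alpha = alpha, decimals = 0))
    }
  }
  shares <- lapply(split(part$fma_total, part$group),
                   cohort_classification_shares, bands = bands)
  structure(list(participants = part, comparisons = comparisons,
                 shares = shares, failures = failures),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle: %d participants, %d failure(s)>\n",
              nrow(x$participants), length(x$failures)))
  if (!is.null(x$comparisons)) print(x$comparisons)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `participants.csv`, `comparisons.csv` (when present), one
#' `shares_<group>.csv` per group, and a `bundle.json` with everything.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$comparisons))
    utils::write.csv(bundle$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  for (g in names(bundle$shares))
    utils::write.csv(bundle$shares[[g]],
                     file.path(dir, paste0("shares_", g, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(
    list(participants = bundle$participants,
         comparisons = bundle$comparisons,
         shares = bundle$shares,
         failures = bundle$failures),
    file.path(dir, "bundle.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
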