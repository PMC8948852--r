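# Semi-automated Fugl-Meyer upper-extremity motor scoring.
#
# 33 ordinal items (0/1/2), maximum 66. Thirty items are scored manually by
# the therapist (movements and qualities the skeleton stream cannot capture:
# rotation, pronation/supination, retraction, grip, reflexes...). The three
# flexor/extensor-synergy items that reduce to a reachable joint angle --
# shoulder abduction, elbow flexion, elbow extension in section A-II
# ("voluntary movement within synergies") -- are scored automatically from
# the measured AROM.

#' Blank 33-item Fugl-Meyer upper-extremity motor sheet
#'
#' Standard item layout: A-I reflex activity (2), A-II movement within
#' synergies (9, of which 3 are automated), A-III mixing synergies (3),
#' A-IV out of synergy (3), A-V normal reflex activity (1), B wrist (5),
#' C hand (7), D coordination/speed (3). Scores start unset (`NA`).
#'
#' @return data.frame with columns `item_id`, `section`, `label`, `mode`
#'   (`"manual"`/`"automated"`), `movement` (automated items only), `score`.
#' @export
fma_sheet_template <- function() {
  it <- function(id, section, label, mode = "manual", movement = NA_character_)
    data.frame(item_id = id, section = section, label = label, mode = mode,
               movement = movement, score = NA_integer_,
               stringsAsFactors = FALSE)
  rbind(
    it("A1-1", "A-I", "Biceps flexor reflex"),
    it("A1-2", "A-I", "Triceps extensor reflex"),
    it("A2-1", "A-II", "Shoulder retraction"),
    it("A2-2", "A-II", "Shoulder elevation"),
    it("A2-3", "A-II", "Shoulder abduction (90 deg)", "automated",
       "shoulder_abduction"),
    it("A2-4", "A-II", "Shoulder external rotation"),
    it("A2-5", "A-II", "Elbow flexion", "automated", "elbow_flexion"),
    it("A2-6", "A-II", "Forearm supination"),
    it("A2-7", "A-II", "Shoulder adduction / internal rotation"),
    it("A2-8", "A-II", "Elbow extension", "automated", "elbow_extension"),
    it("A2-9", "A-II", "Forearm pronation"),
    it("A3-1", "A-III", "Hand to lumbar spine"),
    it("A3-2", "A-III", "Shoulder flexion to 90 deg, elbow extended"),
    it("A3-3", "A-III", "Pronation/supination, elbow at 90 deg"),
    it("A4-1", "A-IV", "Shoulder abduction to 90 deg, elbow extended"),
    it("A4-2", "A-IV", "Shoulder flexion 90-180 deg"),
    it("A4-3", "A-IV", "Pronation/supination, elbow extended"),
    it("A5-1", "A-V", "Normal reflex activity"),
    it("B-1", "B", "Wrist stability, elbow at 90 deg"),
    it("B-2", "B", "Wrist flexion/extension, elbow at 90 deg"),
    it("B-3", "B", "Wrist stability, elbow extended"),
    it("B-4", "B", "Wrist flexion/extension, elbow extended"),
    it("B-5", "B", "Wrist circumduction"),
    it("C-1", "C", "Finger mass flexion"),
    it("C-2", "C", "Finger mass extension"),
    it("C-3", "C", "Hook grasp"),
    it("C-4", "C", "Lateral pinch"),
    it("C-5", "C", "Pincer grasp"),
    it("C-6", "C", "Cylinder grasp"),
    it("C-7", "C", "Spherical grasp"),
    it("D-1", "D", "Tremor"),
    it("D-2", "D", "Dysmetria"),
    it("D-3", "D", "Speed"))
}

#' Default angle thresholds for the automated synergy items
#'
#' Angle cutoffs mapping a measured AROM to the 0/1/2 ordinal: score 2 at or
#' above `full`, 1 at or above `partial`, else 0. All angles in degrees;
#' elbow angles use the included-angle convention (180 = straight), so the
#' elbow-extension cutoffs are high included angles. Defaults sit at
#' clinically typical full/partial ranges and are overridable.
#'
#' @return Named list per movement with elements `full` and `partial`.
#' @export
a2_default_thresholds <- function() {
  list(shoulder_abduction = list(full = 150, partial = 90),
       elbow_flexion = list(full = 130, partial = 60),
       elbow_extension = list(full = 160, partial = 120))
}

.check_thresholds <- function(th) {
  for (m in names(th)) {
    t <- th[[m]]
    if (is.null(t$full) || is.null(t$partial) ||
        !(0 < t$partial && t$partial < t$full && t$full <= 180))
      stop("invalid thresholds for ", m,
           ": need 0 < partial < full <= 180", call. = FALSE)
  }
  th
}

#' Score one automated synergy item from a measured AROM
#'
#' @param arom An `arom_result` (from [extract_arom()]) or a plain angle in
#'   degrees.
#' @param movement `"shoulder_abduction"`, `"elbow_flexion"` or
#'   `"elbow_extension"`; taken from `arom` when it is an `arom_result` whose
#'   movement matches a threshold entry.
#' @param thresholds See [a2_default_thresholds()].
#' @return Integer score 0, 1 or 2.
#' @export
#' @examples
#' score_a2_item(170, "shoulder_abduction")  # 2
#' score_a2_item(100, "shoulder_abduction")  # 1
score_a2_item <- function(arom, movement = NULL,
                          thresholds = a2_default_thresholds()) {
  .check_thresholds(thresholds)
  if (inherits(arom, "arom_result")) {
    if (is.null(movement)) movement <- arom$movement
    arom <- arom$arom
  }
  if (is.null(movement) || !movement %in% names(thresholds))
    stop("no thresholds configured for movement: ",
         if (is.null(movement)) "<missing>" else movement, call. = FALSE)
  t <- thresholds[[movement]]
  if (arom >= t$full) 2L else if (arom >= t$partial) 1L else 0L
}

#' Assemble a complete 33-item sheet from manual items and automated scores
#'
#' @param manual_items data.frame of the 30 manual items (columns `item_id`
#'   and `score` at minimum), all scored 0/1/2.
#' @param automated_scores Named vector or list mapping movement
#'   (`shoulder_abduction`, `elbow_flexion`, `elbow_extension`) to 0/1/2.
#' @param participant,side Optional identifiers stored as attributes.
#' @return Complete sheet data.frame of class `fma_sheet` (33 rows, all
#'   scores set).
#' @export
assemble_sheet <- function(manual_items, automated_scores,
                           participant = NA, side = NA) {
  sheet <- fma_sheet_template()
  if (anyDuplicated(manual_items$item_id))
    stop("schema error: duplicated item_id in manual items", call. = FALSE)
  manual_ids <- sheet$item_id[sheet$mode == "manual"]
  unknown <- setdiff(manual_items$item_id, sheet$item_id)
  if (length(unknown))
    stop("schema error: unknown item_id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(manual_ids, manual_items$item_id)
  if (length(missing))
    stop("incomplete sheet: missing manual item(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sc <- manual_items$score[match(manual_ids, manual_items$item_id)]
  if (any(is.na(sc)) || !all(sc %in% 0:2))
    stop("all manual item scores must be set to 0, 1 or 2", call. = FALSE)
  sheet$score[sheet$mode == "manual"] <- as.integer(sc)
  auto <- sheet[sheet$mode == "automated", ]
  for (k in seq_len(nrow(auto))) {
    mv <- auto$movement[k]
    if (is.null(automated_scores[[mv]]))
      stop("incomplete sheet: missing automated score for ", mv, call. = FALSE)
    s <- as.integer(automated_scores[[mv]])
    if (!s %in% 0:2) stop("automated score for ", mv, " must be 0, 1 or 2",
                          call. = FALSE)
    sheet$score[sheet$item_id == auto$item_id[k]] <- s
  }
  attr(sheet, "participant") <- participant
  attr(sheet, "side") <- side
  class(sheet) <- c("fma_sheet", "data.frame")
  sheet
}

#' Total Fugl-Meyer motor score of a complete sheet
#'
#' @param sheet A complete sheet from [assemble_sheet()] (or any data.frame
#'   with 33 set `score` values in 0..2).
#' @return Integer total in 0..66.
#' @export
total_score <- function(sheet) {
  if (nrow(sheet) != 33L)
    stop("a sheet has exactly 33 items, got ", nrow(sheet), call. = FALSE)
  if (any(is.na(sheet$score)))
    stop("incomplete sheet: unset item(s): ",
         paste(sheet$item_id[is.na(sheet$score)], collapse = ", "),
         call. = FALSE)
  if (!all(sheet$score %in% 0:2))
    stop("item scores must be 0, 1 or 2", call. = FALSE)
  sum(as.integer(sheet$score))
}

#' Capacity band schemes for the total motor score
#'
#' Three published-style banding schemes of the 0-66 total:
#' \describe{
#'   \item{interface}{closed bands 0-22 none, 23-31 low, 32-47 limited,
#'     53-66 total; totals 48-52 fall in a gap and classify as
#'     `"unclassified"`.}
#'   \item{discussion}{31-47 limited, 47-52 notable, 52-66 total with shared
#'     endpoints (the higher band wins at a shared endpoint); below 31 the
#'     interface's none/low bands apply.}
#'   \item{hybrid}{default; half-open partition of 0-66 with no gaps or
#'     overlaps: [0,23) none, [23,31) low, [31,47) limited, [47,52) notable,
#'     [52,66] total.}
#' }
#'
#' @param scheme `"hybrid"` (default), `"interface"` or `"discussion"`.
#' @return data.frame with columns `lower`, `upper` (inclusive integer
#'   bounds), `category`.
#' @export
capacity_bands <- function(scheme = c("hybrid", "interface", "discussion")) {
  scheme <- match.arg(scheme)
  b <- switch(scheme,
    hybrid = data.frame(
      lower = c(0, 23, 31, 47, 52), upper = c(22, 30, 46, 51, 66),
      category = c("none", "low", "limited", "notable", "total")),
    interface = data.frame(
      lower = c(0, 23, 32, 48, 53), upper = c(22, 31, 47, 52, 66),
      category = c("none", "low", "limited", "unclassified", "total")),
    discussion = data.frame(
      lower = c(0, 23, 31, 47, 52), upper = c(22, 30, 47, 52, 66),
      category = c("none", "low", "limited", "notable", "total")))
  attr(b, "scheme") <- scheme
  b
}

#' Classify a total motor score into a capacity category
#'
#' @param total Integer total in 0..66.
#' @param bands A band table from [capacity_bands()].
#' @return Category label.
#' @export
#' @examples
#' classify_capacity(40)  # "limited"
#' classify_capacity(50)  # "notable"
#' classify_capacity(66)  # "total"
classify_capacity <- function(total, bands = capacity_bands("hybrid")) {
  if (length(total) != 1L || is.na(total) || total < 0 || total > 66)
    stop("total must be a single score in 0..66", call. = FALSE)
  hit <- which(bands$lower <= total & total <= bands$upper)
  if (length(hit) == 0L) return("unclassified")
  bands$category[hit[length(hit)]]  # higher band wins at shared endpoints
}

#' Read a manual item sheet CSV
#'
#' Dialect: columns `item_id`, `section`, `label`, `mode`, `score`.
#'
#' @param path File path.
#' @return data.frame of manual items.
#' @export
read_manual_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manual sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}
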