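# Skeleton data model and I/O: 25-joint markerless body-tracking layout.

#' Canonical joint names of the 25-joint skeleton layout
#'
#' The fixed vocabulary of joint names used throughout the package, matching
#' the Kinect-v2 body-tracking skeleton. Lookup by name is total: any name not
#' in this set is rejected at parse time.
#'
#' @return Character vector of 25 joint names.
#' @export
#' @examples
#' joint_names()
joint_names <- function() {
  c("SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder", "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight")
}

.tracking_states <- c("tracked", "inferred", "not_tracked")

#' Construct a single skeleton frame
#'
#' A frame is one time-stamped sample of all 25 joints: a 25 x 3 position
#' matrix in camera space (meters; x to the camera's left, i.e. the
#' participant's right when facing the camera; y up; z from the camera toward
#' the participant) plus a per-joint tracking state.
#'
#' @param frame_index Non-negative integer frame counter.
#' @param positions Numeric 25 x 3 matrix with rownames `joint_names()` and
#'   columns x, y, z (meters).
#' @param timestamp Time in seconds; if `NULL` it is derived downstream from
#'   `frame_index` and the stream rate.
#' @param tracking Named character vector of per-joint states, each one of
#'   `"tracked"`, `"inferred"`, `"not_tracked"`. Defaults to all tracked.
#' @return An object of class `skeleton_frame`.
#' @export
skeleton_frame <- function(frame_index, positions, timestamp = NULL,
                           tracking = NULL) {
  jn <- joint_names()
  if (is.null(tracking)) tracking <- stats::setNames(rep("tracked", 25L), jn)
  stopifnot(is.matrix(positions), ncol(positions) == 3L)
  positions <- positions[jn, , drop = FALSE]
  colnames(positions) <- c("x", "y", "z")
  structure(
    list(frame_index = as.integer(frame_index),
         timestamp = if (is.null(timestamp)) NA_real_ else as.numeric(timestamp),
         positions = positions,
         tracking = tracking[jn]),
    class = "skeleton_frame")
}

#' Construct a skeleton stream
#'
#' @param frames List of [skeleton_frame()] objects, ordered by
#'   strictly-increasing `frame_index`.
#' @param rate Nominal sampling rate in Hz (default 30, the sensor's rate).
#' @param metadata Named list (participant id, side, acquisition condition...).
#' @return An object of class `skeleton_stream`.
#' @export
skeleton_stream <- function(frames, rate = 30, metadata = list()) {
  if (length(frames) == 0L)
    stop("empty stream: a skeleton_stream needs at least one frame", call. = FALSE)
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  frames <- frames[order(idx)]
  idx <- sort(idx)
  if (any(diff(idx) <= 0))
    stop("frame_index must be strictly increasing", call. = FALSE)
  # derive timestamps where absent: frame_index / rate
  frames <- lapply(frames, function(f) {
    if (is.na(f$timestamp)) f$timestamp <- f$frame_index / rate
    f
  })
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (any(diff(ts) < 0))
    stop("timestamps must be non-decreasing", call. = FALSE)
  structure(list(frames = frames, rate = rate, metadata = metadata),
            class = "skeleton_stream")
}

#' @export
length.skeleton_stream <- function(x) length(x$frames)

#' @export
print.skeleton_stream <- function(x, ...) {
  cat(sprintf("<skeleton_stream: %d frames @ %g Hz>\n", length(x$frames), x$rate))
  if (length(x$metadata)) {
    md <- vapply(x$metadata, function(v) paste(format(v), collapse = ","),
                 character(1))
    cat("  ", paste(names(md), md, sep = "=", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Validate a skeleton frame
#'
#' Total validator: reports invariant violations as a character vector of
#' issue descriptors and never throws, whatever the frame content. An empty
#' result means the frame satisfies all invariants (all 25 joints present,
#' finite coordinates, known tracking states).
#'
#' @param frame A [skeleton_frame()] (or anything; arbitrary input yields
#'   issues, not errors).
#' @return Character vector of issues, empty if the frame is valid.
#' @export
#' @examples
#' f <- pose_to_skeleton(arm_pose("right", 90, 180))
#' validate_frame(f)  # character(0)
validate_frame <- function(frame) {
  issues <- character(0)
  if (!inherits(frame, "skeleton_frame") || !is.list(frame))
    return("not a skeleton_frame object")
  jn <- joint_names()
  pos <- frame$positions
  if (!is.matrix(pos) || ncol(pos) != 3L)
    return("positions is not a 25 x 3 matrix")
  missing <- setdiff(jn, rownames(pos))
  for (j in missing) issues <- c(issues, paste0("missing joint: ", j))
  extra <- setdiff(rownames(pos), jn)
  for (j in extra) issues <- c(issues, paste0("unknown joint: ", j))
  present <- intersect(jn, rownames(pos))
  bad <- present[!apply(is.finite(pos[present, , drop = FALSE]), 1L, all)]
  for (j in bad) issues <- c(issues, paste0("non-finite coordinate: ", j))
  trk <- frame$tracking
  badstate <- names(trk)[!trk %in% .tracking_states]
  for (j in badstate)
    issues <- c(issues, paste0("invalid tracking state: ", j))
  if (length(frame$frame_index) != 1L || is.na(frame$frame_index) ||
      frame$frame_index < 0L)
    issues <- c(issues, "frame_index must be a single non-negative integer")
  issues
}

# ---- I/O ---------------------------------------------------------------
# Two interchangeable on-disk dialects:
#  * long CSV: frame_index,timestamp_s,joint,x_m,y_m,z_m,tracking_state
#  * JSON-lines (.jsonl): one frame object per line

.is_jsonl <- function(path) grepl("\\.jsonl$", path, ignore.case = TRUE)

#' Read a skeleton stream from disk
#'
#' Accepts the long CSV dialect (columns `frame_index`, `timestamp_s`,
#' `joint`, `x_m`, `y_m`, `z_m`, `tracking_state`; one row per joint per
#' frame) or, for paths ending in `.jsonl`, a JSON-lines dialect with one
#' frame object per line. Joint names are validated against the closed
#' 25-name vocabulary; each frame must carry all 25 joints.
#'
#' @param path File path.
#' @param rate Nominal rate in Hz used when timestamps are absent.
#' @param metadata Optional metadata list attached to the stream.
#' @return A [skeleton_stream()].
#' @export
read_skeleton_stream <- function(path, rate = 30, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (.is_jsonl(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
      stop("empty stream file: ", path, call. = FALSE)
    frames <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e)
                        stop(sprintf("parse error at line %d of %s: %s",
                                     i, path, conditionMessage(e)),
                             call. = FALSE))
      .frame_from_record(rec, where = sprintf("line %d", i))
    })
  } else {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e)
                     stop("parse error reading ", path, ": ",
                          conditionMessage(e), call. = FALSE))
    need <- c("frame_index", "timestamp_s", "joint", "x_m", "y_m", "z_m",
              "tracking_state")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("stream CSV missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (nrow(df) == 0L) stop("empty stream file: ", path, call. = FALSE)
    bad <- which(!df$joint %in% joint_names())
    if (length(bad))
      stop(sprintf("schema error: unknown joint name '%s' at data row %d",
                   df$joint[bad[1]], bad[1]), call. = FALSE)
    badnum <- which(!is.finite(df$x_m) | !is.finite(df$y_m) | !is.finite(df$z_m))
    # non-finite coordinates are carried through; validate_frame reports them
    frames <- lapply(split(df, df$frame_index), function(g) {
      if (anyDuplicated(g$joint))
        stop("schema error: duplicated joint in frame ", g$frame_index[1],
             call. = FALSE)
      if (nrow(g) != 25L)
        stop(sprintf("schema error: frame %d has %d joints, expected 25",
                     g$frame_index[1], nrow(g)), call. = FALSE)
      pos <- as.matrix(g[, c("x_m", "y_m", "z_m")])
      rownames(pos) <- g$joint
      ts <- g$timestamp_s[1]
      skeleton_frame(g$frame_index[1], pos,
                     timestamp = if (is.na(ts)) NULL else ts,
                     tracking = stats::setNames(g$tracking_state, g$joint))
    })
    frames <- frames[order(vapply(frames, `[[`, integer(1), "frame_index"))]
  }
  skeleton_stream(frames, rate = rate, metadata = metadata)
}

.frame_from_record <- function(rec, where) {
  jn <- joint_names()
  js <- rec$joints
  if (is.null(js)) stop("schema error at ", where, ": no 'joints' field",
                        call. = FALSE)
  unknown <- setdiff(names(js), jn)
  if (length(unknown))
    stop("schema error at ", where, ": unknown joint name '", unknown[1], "'",
         call. = FALSE)
  if (length(setdiff(jn, names(js))))
    stop("schema error at ", where, ": frame does not carry all 25 joints",
         call. = FALSE)
  pos <- t(vapply(jn, function(j) unlist(js[[j]][c("x", "y", "z")]),
                  numeric(3)))
  trk <- vapply(jn, function(j) {
    s <- js[[j]][["state"]]
    if (is.null(s)) "tracked" else as.character(s)
  }, character(1))
  skeleton_frame(rec$frame_index, pos,
                 timestamp = rec$timestamp_s,
                 tracking = stats::setNames(trk, jn))
}

#' Write a skeleton stream to disk
#'
#' Writes the long CSV dialect, or JSON-lines when `path` ends in `.jsonl`.
#' Positions survive a read/write round trip to better than 1e-9 m.
#'
#' @param stream A [skeleton_stream()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_skeleton_stream <- function(stream, path) {
  stopifnot(inherits(stream, "skeleton_stream"))
  if (length(stream$frames) == 0L)
    stop("refusing to write a 0-frame stream", call. = FALSE)
  if (.is_jsonl(path)) {
    lines <- vapply(stream$frames, function(f) {
      js <- lapply(joint_names(), function(j)
        list(x = f$positions[j, "x"], y = f$positions[j, "y"],
             z = f$positions[j, "z"], state = unname(f$tracking[[j]])))
      names(js) <- joint_names()
      jsonlite::toJSON(list(frame_index = f$frame_index,
                            timestamp_s = f$timestamp, joints = js),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
  } else {
    rows <- do.call(rbind, lapply(stream$frames, function(f) {
      data.frame(frame_index = f$frame_index,
                 timestamp_s = f$timestamp,
                 joint = rownames(f$positions),
                 x_m = f$positions[, "x"],
                 y_m = f$positions[, "y"],
                 z_m = f$positions[, "z"],
                 tracking_state = unname(f$tracking[rownames(f$positions)]),
                 row.names = NULL)
    }))
    for (col in c("x_m", "y_m", "z_m", "timestamp_s"))
      rows[[col]] <- formatC(rows[[col]], digits = 15, format = "g")
    tryCatch(utils::write.csv(rows, path, row.names = FALSE, quote = FALSE),
             error = function(e) stop("cannot write ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  invisible(path)
}
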