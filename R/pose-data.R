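#' @keywords internal
"_PACKAGE"

# Upper-limb landmarks that must be present in every frame. Names follow the
# 33-point whole-body pose topology (left_shoulder = 11, right_shoulder = 12,
# left_elbow = 13, right_elbow = 14, left_wrist = 15, right_wrist = 16,
# left_hip = 23, right_hip = 24); names are canonical here, indices are a
# backend adapter detail.
REQUIRED_LANDMARKS <- c(
  "left_hip", "right_hip",
  "left_shoulder", "right_shoulder",
  "left_elbow", "right_elbow",
  "left_wrist", "right_wrist"
)

#' Required upper-limb landmark names
#'
#' The eight landmark names every [landmark_sequence()] frame must carry
#' (hip, shoulder, elbow, wrist on both sides).
#'
#' @return Character vector of landmark names.
#' @export
required_landmarks <- function() REQUIRED_LANDMARKS

#' Construct a 2D pose-landmark sequence
#'
#' A `landmark_sequence` holds per-frame 2D image coordinates and a
#' visibility score in `[0, 1]` for named body landmarks, together with the
#' frame rate and image geometry. Coordinates use the image convention:
#' origin at the top-left corner, x rightward, y downward, units of pixels
#' (or normalized to `[0, 1]` when `normalized = TRUE`, in which case
#' [normalize_to_pixels()] must be applied before any kinematics).
#'
#' Landmarks missing from a frame are filled in with visibility 0 and `NA`
#' coordinates so that every frame carries the full required set; such
#' points are never used for angle computation.
#'
#' @param data Data frame in long format with columns `frame`, `time_s`,
#'   `landmark`, `x`, `y`, `visibility`; one row per frame x landmark.
#' @param fps Frames per second (> 0). Must agree with the median frame
#'   interval within 5 per cent.
#' @param image_width_px,image_height_px Positive image dimensions in pixels.
#' @param metadata Named list of free-form metadata (participant, side,
#'   task, setting, ...). Stored and round-tripped through CSV.
#' @param normalized Logical; `TRUE` when coordinates are normalized to
#'   `[0, 1]` by image width and height.
#' @return An object of class `landmark_sequence`.
#' @seealso [read_landmark_csv()], [normalize_to_pixels()]
#' @export
landmark_sequence <- function(data, fps,
                              image_width_px = 1920L,
                              image_height_px = 1080L,
                              metadata = list(),
                              normalized = FALSE) {
  cols <- c("frame", "time_s", "landmark", "x", "y", "visibility")
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("`data` lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[, cols]
  data$frame <- as.integer(data$frame)
  data$landmark <- as.character(data$landmark)
  data <- .fill_missing_landmarks(data)
  data <- data[order(data$frame, match(data$landmark, unique(data$landmark))), ]
  rownames(data) <- NULL

  obj <- structure(
    list(
      data = data,
      fps = as.numeric(fps),
      image_width_px = as.integer(image_width_px),
      image_height_px = as.integer(image_height_px),
      metadata = metadata
    ),
    normalized = isTRUE(normalized),
    class = "landmark_sequence"
  )
  validate_landmark_sequence(obj)
  obj
}

# Ensure every frame carries every required landmark; absentees get
# visibility 0 and NA coordinates (flagged, never dropped).
.fill_missing_landmarks <- function(data) {
  frames <- unique(data$frame)
  need <- expand.grid(frame = frames, landmark = REQUIRED_LANDMARKS,
                      stringsAsFactors = FALSE)
  have <- paste(data$frame, data$landmark)
  miss <- need[!(paste(need$frame, need$landmark) %in% have), , drop = FALSE]
  if (nrow(miss) == 0) return(data)
  tmap <- data$time_s[match(miss$frame, data$frame)]
  fill <- data.frame(frame = miss$frame, time_s = tmap,
                     landmark = miss$landmark,
                     x = NA_real_, y = NA_real_, visibility = 0,
                     stringsAsFactors = FALSE)
  rbind(data, fill)
}

#' Validate a landmark sequence
#'
#' Checks the structural invariants of a [landmark_sequence()]: at least one
#' frame; strictly increasing frame index and time; unique frame indices;
#' visibility in `[0, 1]`; finite coordinates wherever visibility is
#' positive; all required landmarks present in every frame; and frame rate
#' consistent with the median inter-frame interval within 5 per cent.
#'
#' @param seq A `landmark_sequence`.
#' @return `seq`, invisibly, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_landmark_sequence <- function(seq) {
  if (!inherits(seq, "landmark_sequence")) {
    stop("not a landmark_sequence", call. = FALSE)
  }
  d <- seq$data
  if (nrow(d) == 0) stop("sequence must contain at least 1 frame", call. = FALSE)
  if (!is.finite(seq$fps) || seq$fps <= 0) {
    stop("invariant violated: fps must be > 0", call. = FALSE)
  }
  if (seq$image_width_px <= 0 || seq$image_height_px <= 0) {
    stop("invariant violated: image dimensions must be positive", call. = FALSE)
  }

  ft <- unique(d[, c("frame", "time_s")])
  if (anyDuplicated(ft$frame)) {
    dup <- ft$frame[duplicated(ft$frame)][1]
    stop("invariant violated: duplicated frame_index (frame ", dup, ")",
         call. = FALSE)
  }
  ft <- ft[order(ft$frame), ]
  if (any(ft$frame < 0)) {
    stop("invariant violated: frame_index must be nonnegative", call. = FALSE)
  }
  if (nrow(ft) > 1) {
    bad <- which(diff(ft$time_s) <= 0)
    if (length(bad) > 0) {
      stop("invariant violated: time_s not strictly increasing at frame ",
           ft$frame[bad[1] + 1], call. = FALSE)
    }
    dt <- stats::median(diff(ft$time_s))
    if (abs(dt - 1 / seq$fps) > 0.05 / seq$fps) {
      stop("invariant violated: fps (", seq$fps,
           ") inconsistent with median frame interval (", signif(dt, 6), " s)",
           call. = FALSE)
    }
  }
  if (any(d$time_s < 0)) {
    stop("invariant violated: time_s must be >= 0", call. = FALSE)
  }
  if (any(!is.finite(d$visibility)) || any(d$visibility < 0 | d$visibility > 1)) {
    stop("invariant violated: visibility must lie in [0, 1]", call. = FALSE)
  }
  vis <- d$visibility > 0
  if (any(vis & (!is.finite(d$x) | !is.finite(d$y)))) {
    stop("invariant violated: x, y must be finite where visibility > 0",
         call. = FALSE)
  }
  per_frame <- table(d$frame)
  missing_lm <- setdiff(REQUIRED_LANDMARKS, unique(d$landmark))
  if (length(missing_lm) > 0) {
    stop("invariant violated: required landmark(s) absent: ",
         paste(missing_lm, collapse = ", "), call. = FALSE)
  }
  if (any(per_frame < length(REQUIRED_LANDMARKS))) {
    stop("invariant violated: some frames lack required landmarks",
         call. = FALSE)
  }
  invisible(seq)
}

#' Number of frames in a sequence
#' @param seq A `landmark_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(unique(seq$data$frame))

#' Extract the trajectory of one landmark
#'
#' @param seq A `landmark_sequence`.
#' @param name Landmark name (e.g. `"right_shoulder"`).
#' @return Data frame with columns `frame`, `time_s`, `x`, `y`, `visibility`,
#'   ordered by frame.
#' @export
landmark_track <- function(seq, name) {
  d <- seq$data[seq$data$landmark == name, , drop = FALSE]
  if (nrow(d) == 0) stop("landmark '", name, "' not present", call. = FALSE)
  d <- d[order(d$frame), c("frame", "time_s", "x", "y", "visibility")]
  rownames(d) <- NULL
  d
}

#' Resolve the ipsilateral landmark names for one body side
#'
#' Maps a side to the hip/shoulder/elbow/wrist landmark names used for the
#' shoulder angle (vertex shoulder, rays to the ipsilateral hip and elbow)
#' and elbow angle (vertex elbow, rays to shoulder and wrist).
#'
#' @param side `"left"` or `"right"`.
#' @return An object of class `side_spec`: a list with elements `side`,
#'   `hip`, `shoulder`, `elbow`, `wrist`.
#' @export
side_spec <- function(side = c("left", "right")) {
  side <- match.arg(side)
  structure(
    list(
      side = side,
      hip = paste0(side, "_hip"),
      shoulder = paste0(side, "_shoulder"),
      elbow = paste0(side, "_elbow"),
      wrist = paste0(side, "_wrist")
    ),
    class = "side_spec"
  )
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat("<landmark_sequence>\n")
  cat("  frames:", n_frames(x), " fps:", x$fps, "\n")
  cat("  image:", x$image_width_px, "x", x$image_height_px, "px",
      if (isTRUE(attr(x, "normalized"))) " (normalized coordinates)" else "",
      "\n", sep = "")
  cat("  landmarks:", length(unique(x$data$landmark)), "\n")
  if (length(x$metadata) > 0) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- CSV I/O --------------------------------------------------------------
# Long-format dialect, UTF-8. Optional `# key=value` comment lines precede
# the header `frame,time_s,landmark,x,y,visibility`. Coordinates are pixels
# unless a `# coordinates=normalized` line is present. Numbers are written
# with %.17g so that read(write(seq)) is bit-exact.

LANDMARK_CSV_HEADER <- c("frame", "time_s", "landmark", "x", "y", "visibility")

#' Read a landmark CSV file
#'
#' Reads the long-format landmark dialect written by [write_landmark_csv()]:
#' optional `# key=value` metadata comment lines (fps, image_width_px,
#' image_height_px, participant, side, task, setting, ...), a header row
#' `frame,time_s,landmark,x,y,visibility`, then one row per frame x
#' landmark. When a `# coordinates=normalized` line is present the sequence
#' is flagged normalized and [normalize_to_pixels()] is required before
#' kinematics. Missing required landmarks are filled with visibility 0.
#' If no `fps` metadata line is present the frame rate is inferred from the
#' median frame interval.
#'
#' @param path Path to a CSV file.
#' @return A validated [landmark_sequence()].
#' @export
read_landmark_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^#", lines)
  n_head <- 0L
  while (n_head < length(lines) && is_comment[n_head + 1L]) n_head <- n_head + 1L
  meta <- .parse_meta_comments(lines[seq_len(n_head)])

  body <- lines[(n_head + 1L):length(lines)]
  if (length(body) < 1) stop("malformed file: no header row", call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), LANDMARK_CSV_HEADER)) {
    bad <- setdiff(trimws(header), LANDMARK_CSV_HEADER)
    if (length(bad) == 0) bad <- setdiff(LANDMARK_CSV_HEADER, trimws(header))
    stop("malformed header: expected '",
         paste(LANDMARK_CSV_HEADER, collapse = ","),
         "'; offending column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  d <- utils::read.csv(text = paste(body, collapse = "\n"),
                       stringsAsFactors = FALSE)

  normalized <- identical(meta$coordinates, "normalized")
  meta$coordinates <- NULL
  fps <- if (!is.null(meta$fps)) as.numeric(meta$fps) else {
    times <- sort(unique(d$time_s))
    if (length(times) > 1) 1 / stats::median(diff(times)) else 30
  }
  w <- if (!is.null(meta$image_width_px)) as.integer(meta$image_width_px) else 1920L
  h <- if (!is.null(meta$image_height_px)) as.integer(meta$image_height_px) else 1080L
  meta$fps <- meta$image_width_px <- meta$image_height_px <- NULL

  landmark_sequence(d, fps = fps, image_width_px = w, image_height_px = h,
                    metadata = meta, normalized = normalized)
}

.parse_meta_comments <- function(lines) {
  meta <- list()
  for (ln in lines) {
    ln <- sub("^#\\s*", "", ln)
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    meta[[key]] <- val
  }
  meta
}

#' Write a landmark CSV file
#'
#' Serializes a [landmark_sequence()] to the long-format dialect read by
#' [read_landmark_csv()]. Coordinates and times are written at full
#' precision (`%.17g`) so the round trip is bit-exact.
#'
#' @param seq A valid `landmark_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(seq, path) {
  validate_landmark_sequence(seq)
  d <- seq$data
  hdr <- c(
    sprintf("# fps=%.17g", seq$fps),
    sprintf("# image_width_px=%d", seq$image_width_px),
    sprintf("# image_height_px=%d", seq$image_height_px)
  )
  if (isTRUE(attr(seq, "normalized"))) hdr <- c(hdr, "# coordinates=normalized")
  for (k in names(seq$metadata)) {
    hdr <- c(hdr, sprintf("# %s=%s", k, as.character(seq$metadata[[k]])))
  }
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  rows <- sprintf("%d,%s,%s,%s,%s,%s",
                  d$frame, num(d$time_s), d$landmark,
                  num(d$x), num(d$y), num(d$visibility))
  out <- c(hdr, paste(LANDMARK_CSV_HEADER, collapse = ","), rows)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Convert normalized coordinates to pixel space
#'
#' Pose backends emit coordinates normalized independently by image width
#' and height. The interior-angle formula is not invariant to that
#' non-uniform scaling (unless width equals height), so conversion to pixels
#' is mandatory before computing joint angles.
#'
#' @param seq A `landmark_sequence` with coordinates in `[0, 1]`.
#' @param width,height Target image dimensions in pixels (> 0); default to
#'   the dimensions stored on `seq`.
#' @return A pixel-space `landmark_sequence`; the conversion is recorded in
#'   the metadata.
#' @export
normalize_to_pixels <- function(seq, width = seq$image_width_px,
                                height = seq$image_height_px) {
  validate_landmark_sequence(seq)
  if (width <= 0 || height <= 0) stop("width and height must be > 0", call. = FALSE)
  d <- seq$data
  ok <- is.na(d$x) | (d$x >= 0 & d$x <= 1 & d$y >= 0 & d$y <= 1)
  if (!all(ok)) {
    stop("coordinates outside [0, 1]: input appears to be in pixel space already",
         call. = FALSE)
  }
  d$x <- d$x * width
  d$y <- d$y * height
  out <- seq
  out$data <- d
  out$image_width_px <- as.integer(width)
  out$image_height_px <- as.integer(height)
  out$metadata$coordinate_conversion <- sprintf("normalized_to_%dx%d",
                                                as.integer(width), as.integer(height))
  attr(out, "normalized") <- FALSE
  validate_landmark_sequence(out)
  out
}

#' Build a landmark sequence via a pose-estimation backend adapter
#'
#' The adapter contract: `backend` is a function called once per frame with
#' the frame index (0-based) and the opaque `video_source`; it returns a
#' data frame with columns `landmark`, `x`, `y`, `visibility` holding the 33
#' (or at least the required 8) topology landmarks with coordinates
#' normalized to `[0, 1]`, or `NULL` on failure. Failed frames are retained
#' with all visibilities 0 rather than dropped, so frame accounting stays
#' intact. The assembled sequence is converted to pixel space.
#'
#' @param video_source Opaque handle passed through to the backend.
#' @param backend Adapter function `(frame_index, video_source) -> data.frame`.
#' @param n_frames Number of frames to request.
#' @param fps Frame rate of the source.
#' @param image_width_px,image_height_px Source image dimensions.
#' @param metadata Metadata list stored on the result.
#' @return A pixel-space [landmark_sequence()].
#' @export
from_pose_backend <- function(video_source, backend, n_frames, fps,
                              image_width_px = 1920L, image_height_px = 1080L,
                              metadata = list()) {
  if (!is.function(backend)) {
    stop("pose backend unavailable: `backend` must be a function implementing ",
         "the adapter contract", call. = FALSE)
  }
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    res <- tryCatch(backend(i - 1L, video_source), error = function(e) NULL)
    if (is.null(res) || !is.data.frame(res) ||
        !all(c("landmark", "x", "y", "visibility") %in% names(res))) {
      res <- data.frame(landmark = REQUIRED_LANDMARKS,
                        x = NA_real_, y = NA_real_, visibility = 0,
                        stringsAsFactors = FALSE)
    }
    res$frame <- i - 1L
    res$time_s <- (i - 1L) / fps
    frames[[i]] <- res[, c("frame", "time_s", "landmark", "x", "y", "visibility")]
  }
  seq_norm <- landmark_sequence(do.call(rbind, frames), fps = fps,
                                image_width_px = image_width_px,
                                image_height_px = image_height_px,
                                metadata = metadata, normalized = TRUE)
  normalize_to_pixels(seq_norm)
}
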