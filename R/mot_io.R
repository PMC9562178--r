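#' Construct a MOT sequence
#'
#' A `mot_sequence` is the canonical in-memory container for per-frame
#' bounding-box detections: one data frame row per box, in center/size
#' parameterization, plus the image dimensions the boxes live in.
#'
#' @param detections data frame with columns `frame` (integer, >= 1),
#'   `id` (integer plant ID >= 1, or `NA` for unassigned), `cx`, `cy`
#'   (box-center pixel coordinates, origin top-left, y down), `w`, `h`
#'   (box width/height in pixels, > 0) and `conf` (confidence in
#'   \[0, 1\]). Zero rows are allowed.
#' @param image_width,image_height image dimensions in pixels.
#' @param name identifier string for the sequence.
#'
#' @return An object of class `mot_sequence`: a list with elements
#'   `detections`, `image_width`, `image_height`, `name`.
#' @export
#' @examples
#' d <- data.frame(frame = 1L, id = 3L, cx = 125, cy = 220,
#'                 w = 50, h = 40, conf = 1)
#' mot_sequence(d, image_width = 810, image_height = 1080)
mot_sequence <- function(detections = empty_detections(),
                         image_width = 810, image_height = 1080,
                         name = "seq") {
  detections <- as.data.frame(detections)
  required <- c("frame", "id", "cx", "cy", "w", "h", "conf")
  missing_cols <- setdiff(required, names(detections))
  if (length(missing_cols))
    stop("detections lack column(s): ", paste(missing_cols, collapse = ", "))
  detections <- detections[required]
  if (nrow(detections)) {
    validate_detections(detections)
    detections <- detections[order(detections$frame, detections$id,
                                   detections$cy, detections$cx), ,
                             drop = FALSE]
    rownames(detections) <- NULL
  }
  structure(list(detections = detections,
                 image_width = image_width,
                 image_height = image_height,
                 name = name),
            class = "mot_sequence")
}

#' @export
print.mot_sequence <- function(x, ...) {
  d <- x$detections
  nf <- if (nrow(d)) length(unique(d$frame)) else 0L
  nid <- length(unique(d$id[!is.na(d$id)]))
  cat(sprintf("<mot_sequence '%s'> %d boxes, %d frames, %d IDs, %dx%d px\n",
              x$name, nrow(d), nf, nid, x$image_width, x$image_height))
  invisible(x)
}

#' @export
as.data.frame.mot_sequence <- function(x, ...) x$detections

empty_detections <- function() {
  data.frame(frame = integer(), id = integer(), cx = numeric(),
             cy = numeric(), w = numeric(), h = numeric(), conf = numeric())
}

validate_detections <- function(d) {
  if (any(!is.finite(d$frame)) || any(d$frame < 1))
    stop("frame indices must be >= 1")
  if (any(!is.finite(d$w)) || any(!is.finite(d$h)) ||
      any(d$w <= 0) || any(d$h <= 0))
    stop("box width/height must be positive")
  if (any(!is.finite(d$conf)) || any(d$conf < 0) || any(d$conf > 1))
    stop("confidence must lie in [0, 1]")
  has_id <- !is.na(d$id)
  if (any(d$id[has_id] < 1))
    stop("assigned IDs must be >= 1")
  if (any(has_id) &&
      anyDuplicated(paste(d$frame[has_id], d$id[has_id], sep = "|")))
    stop("duplicate ID within a frame")
  invisible(TRUE)
}

#' Read a MOTChallenge-style text file
#'
#' Parses the comma-separated MOT16 text dialect
#' (`frame,id,bb_left,bb_top,bb_width,bb_height,conf[,x,y,z]`) used for
#' `det.txt`, `gt.txt` and tracker output. Corner coordinates are
#' converted to centers (`cx = bb_left + w/2`, `cy = bb_top + h/2`);
#' `id = -1` maps to unassigned (`NA`).
#'
#' @param path path to an existing MOT text file.
#' @param kind one of `"det"`, `"gt"`, `"result"` (informational; stored
#'   in the sequence name).
#' @param image_width,image_height image dimensions in pixels (the file
#'   format does not carry them).
#' @return A [mot_sequence()].
#' @export
read_mot_file <- function(path, kind = c("det", "gt", "result"),
                          image_width = 810, image_height = 1080) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(mot_sequence(empty_detections(), image_width, image_height,
                        name = basename(path)))
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 7)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected >= 7 comma-separated fields, got %d",
                 bad[1], path, nf[bad[1]]))
  num <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[1:7]), numeric(7)))
  nonnum <- which(colSums(is.na(num)) > 0)
  if (length(nonnum))
    stop(sprintf("malformed line %d in %s: non-numeric field", nonnum[1], path))
  frame <- as.integer(num[1, ]); id <- num[2, ]
  bb_left <- num[3, ]; bb_top <- num[4, ]
  w <- num[5, ]; h <- num[6, ]; conf <- num[7, ]
  if (any(w <= 0) || any(h <= 0)) {
    bad <- which(w <= 0 | h <= 0)[1]
    stop(sprintf("invalid box on line %d in %s: non-positive width/height",
                 bad, path))
  }
  id <- ifelse(id < 0, NA_real_, id)
  d <- data.frame(frame = frame, id = as.integer(id),
                  cx = bb_left + w / 2, cy = bb_top + h / 2,
                  w = w, h = h, conf = conf)
  mot_sequence(d, image_width, image_height, name = basename(path))
}

#' Write a MOT sequence to a MOTChallenge-style text file
#'
#' Inverse of [read_mot_file()]: one line per detection,
#' `frame,id,bb_left,bb_top,bb_width,bb_height,conf,-1,-1,-1`, frames
#' ascending and IDs ascending within frame. Unassigned IDs are written
#' as `-1`.
#'
#' @param seq a [mot_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mot_file <- function(seq, path) {
  stopifnot(inherits(seq, "mot_sequence"))
  d <- seq$detections
  if (!nrow(d)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  validate_detections(d)
  d <- d[order(d$frame, ifelse(is.na(d$id), Inf, d$id), d$cy, d$cx), ,
         drop = FALSE]
  id_out <- ifelse(is.na(d$id), -1, d$id)
  fmt <- function(x) sprintf("%.12g", x)
  lines <- paste(d$frame, fmt(id_out),
                 fmt(d$cx - d$w / 2), fmt(d$cy - d$h / 2),
                 fmt(d$w), fmt(d$h), fmt(d$conf),
                 "-1", "-1", "-1", sep = ",")
  writeLines(lines, path)
  invisible(path)
}

#' Subset a MOT sequence to one frame
#'
#' @param seq a [mot_sequence()].
#' @param frame frame index.
#' @return Data frame of that frame's detections (possibly zero rows).
#' @export
frame_detections <- function(seq, frame) {
  d <- seq$detections
  out <- d[d$frame == frame, , drop = FALSE]
  rownames(out) <- NULL
  out
}
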