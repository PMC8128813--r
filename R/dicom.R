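# Minimal DICOM codec: explicit VR little endian only, covering the CT Image
# and binary Segmentation subsets this package writes. Not a general-purpose
# DICOM implementation.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
SOP_SEG <- "1.2.840.10008.5.1.4.1.1.66.4"

# ---- low-level encoding ----------------------------------------------------

uint_raw <- function(x, size) {
  x <- as.numeric(x)
  out <- raw(size)
  for (i in seq_len(size)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_uint <- function(r) {
  sum(as.numeric(r) * 256^(seq_along(r) - 1))
}

# polynomial content hash -> digit string, for deterministic UIDs
content_digits <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  h1 <- 7; h2 <- 13
  m1 <- 67108859; m2 <- 67108879  # primes < 2^26: products stay exact
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    s <- sum(chunk %% 9973) %% m1
    h1 <- (h1 * 131 + s) %% m1
    h2 <- (h2 * 137 + (sum(abs(chunk)) %% 9967)) %% m2
  }
  sprintf("%.0f%.0f", h1, h2)
}

new_uid <- function(content = NULL) {
  if (is.null(content))
    paste0("2.25.", sprintf("%.0f", as.numeric(Sys.time()) * 1000 %% 1e12))
  else
    paste0("2.25.", content_digits(content))
}

dcm_element <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

encode_value <- function(vr, value) {
  if (vr %in% c("UI")) {
    b <- charToRaw(paste(value, collapse = "\\"))
    if (length(b) %% 2 == 1) b <- c(b, as.raw(0))
    return(b)
  }
  if (vr %in% c("CS", "LO", "SH", "DA", "TM", "PN", "LT", "ST")) {
    b <- charToRaw(paste(value, collapse = "\\"))
    if (length(b) %% 2 == 1) b <- c(b, charToRaw(" "))
    return(b)
  }
  if (vr == "DS") {
    b <- charToRaw(paste(sprintf("%.10g", value), collapse = "\\"))
    if (length(b) %% 2 == 1) b <- c(b, charToRaw(" "))
    return(b)
  }
  if (vr == "IS") {
    b <- charToRaw(paste(sprintf("%d", as.integer(value)), collapse = "\\"))
    if (length(b) %% 2 == 1) b <- c(b, charToRaw(" "))
    return(b)
  }
  if (vr == "US") return(do.call(c, lapply(value, uint_raw, size = 2)))
  if (vr == "UL") return(do.call(c, lapply(value, uint_raw, size = 4)))
  if (vr == "SS") {
    v <- as.integer(value)
    v[v < 0] <- v[v < 0] + 65536L
    return(do.call(c, lapply(v, uint_raw, size = 2)))
  }
  if (vr %in% c("OB", "OW")) return(as.raw(value))
  stop(sprintf("unsupported VR for encoding: %s", vr))
}

encode_element <- function(el) {
  head <- c(uint_raw(el$group, 2), uint_raw(el$element, 2))
  if (el$vr == "SQ") {
    items <- lapply(el$value, function(item) {
      body <- encode_elements(item)
      c(uint_raw(0xFFFE, 2), uint_raw(0xE000, 2), uint_raw(length(body), 4),
        body)
    })
    body <- do.call(c, c(list(raw(0)), items))
    return(c(head, charToRaw("SQ"), raw(2), uint_raw(length(body), 4), body))
  }
  body <- encode_value(el$vr, el$value)
  if (el$vr %in% c("OB", "OW")) {
    c(head, charToRaw(el$vr), raw(2), uint_raw(length(body), 4), body)
  } else {
    if (length(body) > 65534)
      stop("value too long for short-form VR")
    c(head, charToRaw(el$vr), uint_raw(length(body), 2), body)
  }
}

encode_elements <- function(elements) {
  do.call(c, c(list(raw(0)), lapply(elements, encode_element)))
}

write_dicom_file <- function(path, sop_class, sop_instance, dataset) {
  meta <- list(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", sop_class),
    dcm_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", "2.25.999001")
  )
  meta_raw <- encode_elements(meta)
  grplen <- dcm_element(0x0002, 0x0000, "UL", length(meta_raw))
  out <- c(raw(128), charToRaw("DICM"), encode_element(grplen), meta_raw,
           encode_elements(dataset))
  writeBin(out, path)
  invisible(path)
}

# ---- low-level decoding ----------------------------------------------------

tag_key <- function(group, element) sprintf("%04X%04X", group, element)

decode_value <- function(vr, body) {
  if (vr %in% c("UI", "CS", "LO", "SH", "DA", "TM", "PN", "LT", "ST")) {
    s <- rawToChar(body[body != as.raw(0)])
    return(trimws(strsplit(s, "\\", fixed = TRUE)[[1]]))
  }
  if (vr == "DS") {
    s <- trimws(rawToChar(body[body != as.raw(0)]))
    return(as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]]))
  }
  if (vr == "IS") {
    s <- trimws(rawToChar(body[body != as.raw(0)]))
    return(as.integer(strsplit(s, "\\", fixed = TRUE)[[1]]))
  }
  if (vr == "US")
    return(vapply(split(body, ceiling(seq_along(body) / 2)), raw_uint,
                  numeric(1), USE.NAMES = FALSE))
  if (vr == "UL")
    return(vapply(split(body, ceiling(seq_along(body) / 4)), raw_uint,
                  numeric(1), USE.NAMES = FALSE))
  if (vr == "SS") {
    v <- vapply(split(body, ceiling(seq_along(body) / 2)), raw_uint,
                numeric(1), USE.NAMES = FALSE)
    v[v >= 32768] <- v[v >= 32768] - 65536
    return(v)
  }
  body  # OB / OW / UN kept raw
}

# parse elements from raw vector between pos and end; returns list(ds, pos)
parse_elements <- function(buf, pos, end) {
  ds <- list()
  while (pos + 7 <= end) {
    group <- raw_uint(buf[pos:(pos + 1)])
    element <- raw_uint(buf[(pos + 2):(pos + 3)])
    if (group == 0xFFFE) break  # item/sequence delimiter: caller handles
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- raw_uint(buf[(pos + 8):(pos + 11)])
      pos <- pos + 12
    } else {
      len <- raw_uint(buf[(pos + 6):(pos + 7)])
      pos <- pos + 8
    }
    key <- tag_key(group, element)
    if (vr == "SQ") {
      sq_end <- if (len == 0xFFFFFFFF) end else pos + len
      items <- list()
      while (pos + 7 <= sq_end) {
        ig <- raw_uint(buf[pos:(pos + 1)])
        ie <- raw_uint(buf[(pos + 2):(pos + 3)])
        ilen <- raw_uint(buf[(pos + 4):(pos + 7)])
        pos <- pos + 8
        if (ig == 0xFFFE && ie == 0xE0DD) break  # sequence delimiter
        if (!(ig == 0xFFFE && ie == 0xE000))
          stop("malformed sequence item")
        item_end <- if (ilen == 0xFFFFFFFF) sq_end else pos + ilen
        parsed <- parse_elements(buf, pos, item_end)
        items[[length(items) + 1]] <- parsed$ds
        pos <- parsed$pos
        if (ilen == 0xFFFFFFFF) {
          # expect item delimiter
          pos <- pos + 8
        }
      }
      ds[[key]] <- items
    } else {
      if (len == 0xFFFFFFFF) stop("undefined length outside SQ unsupported")
      body <- if (len > 0) buf[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      ds[[key]] <- decode_value(vr, body)
    }
  }
  list(ds = ds, pos = pos)
}

read_dicom_file <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop(sprintf("not a DICOM file: %s", path))
  meta <- parse_elements(buf, 133, length(buf))
  # meta group parsed together with dataset; check transfer syntax
  ts <- meta$ds[[tag_key(0x0002, 0x0010)]]
  if (!is.null(ts) && !identical(ts, TS_EXPLICIT_LE))
    stop("unsupported transfer syntax (explicit VR little endian only)")
  meta$ds
}

# ---- CT series -------------------------------------------------------------

#' Write an image volume as a DICOM CT series
#'
#' One file per axial slice, explicit VR little endian, HU stored as signed
#' 16-bit with identity rescale. UIDs are derived deterministically from the
#' voxel content so repeated writes of the same volume are byte-identical.
#'
#' @param volume an [image_volume()].
#' @param dir output directory (created if needed).
#' @param series_uid optional series instance UID.
#' @return Invisibly, the vector of file paths written.
#' @export
write_ct_dicom <- function(volume, dir, series_uid = NULL) {
  if (!inherits(volume, "image_volume")) stop("volume must be an image_volume")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  if (is.null(series_uid))
    series_uid <- new_uid(c(volume$voxels, volume$spacing, volume$origin))
  study_uid <- paste0(series_uid, ".1")
  frame_uid <- paste0(series_uid, ".2")
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    ipp <- voxel_to_patient(volume, c(1, 1, k))
    px <- as.integer(round(volume$voxels[, , k]))
    px <- pmax(pmin(px, 32767L), -32768L)
    pxv <- px; pxv[pxv < 0] <- pxv[pxv < 0] + 65536L
    pix_raw <- do.call(c, lapply(pxv, uint_raw, size = 2))
    sop_uid <- paste0(series_uid, ".", k)
    dataset <- list(
      dcm_element(0x0008, 0x0016, "UI", SOP_CT),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", k),
      dcm_element(0x0020, 0x0032, "DS", ipp),
      dcm_element(0x0020, 0x0037, "DS",
                  c(volume$orientation[, 1], volume$orientation[, 2])),
      dcm_element(0x0020, 0x0052, "UI", frame_uid),
      dcm_element(0x0028, 0x0002, "US", 1),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[2]),   # Rows (y)
      dcm_element(0x0028, 0x0011, "US", d[1]),   # Columns (x)
      dcm_element(0x0028, 0x0030, "DS", c(volume$spacing[2], volume$spacing[1])),
      dcm_element(0x0018, 0x0050, "DS", volume$spacing[3]),
      dcm_element(0x0028, 0x0100, "US", 16),
      dcm_element(0x0028, 0x0101, "US", 16),
      dcm_element(0x0028, 0x0102, "US", 15),
      dcm_element(0x0028, 0x0103, "US", 1),
      dcm_element(0x0028, 0x1052, "DS", 0),
      dcm_element(0x0028, 0x1053, "DS", 1),
      dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
    )
    paths[k] <- file.path(dir, sprintf("slice_%04d.dcm", k))
    write_dicom_file(paths[k], SOP_CT, sop_uid, dataset)
  }
  invisible(paths)
}

read_ct_dicom_dir <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0)
    stop(sprintf("no DICOM files found in %s", path))
  slices <- lapply(files, read_dicom_file)
  series <- vapply(slices, function(s) {
    u <- s[[tag_key(0x0020, 0x000E)]]
    if (is.null(u)) "" else u
  }, character(1))
  if (length(unique(series)) > 1)
    stop("ambiguous series: directory contains more than one series UID")
  geom_ok <- vapply(slices, function(s) {
    !is.null(s[[tag_key(0x0020, 0x0032)]]) &&
      !is.null(s[[tag_key(0x0020, 0x0037)]]) &&
      !is.null(s[[tag_key(0x0028, 0x0030)]])
  }, logical(1))
  if (!all(geom_ok))
    stop("invalid geometry: missing position/orientation/spacing tags")
  iop <- slices[[1]][[tag_key(0x0020, 0x0037)]]
  dir_x <- iop[1:3]; dir_y <- iop[4:6]
  normal <- c(dir_x[2] * dir_y[3] - dir_x[3] * dir_y[2],
              dir_x[3] * dir_y[1] - dir_x[1] * dir_y[3],
              dir_x[1] * dir_y[2] - dir_x[2] * dir_y[1])
  pos <- t(vapply(slices, function(s) s[[tag_key(0x0020, 0x0032)]],
                  numeric(3)))
  ord <- order(pos %*% normal)
  slices <- slices[ord]; pos <- pos[ord, , drop = FALSE]
  nz <- length(slices)
  rows <- slices[[1]][[tag_key(0x0028, 0x0010)]]
  cols <- slices[[1]][[tag_key(0x0028, 0x0011)]]
  ps <- slices[[1]][[tag_key(0x0028, 0x0030)]]
  dz <- if (nz > 1) {
    proj <- pos %*% normal
    mean(diff(proj))
  } else {
    st <- slices[[1]][[tag_key(0x0018, 0x0050)]]
    if (is.null(st)) 1 else st
  }
  vox <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    body <- s[[tag_key(0x7FE0, 0x0010)]]
    v <- vapply(split(body, ceiling(seq_along(body) / 2)), raw_uint,
                numeric(1), USE.NAMES = FALSE)
    if (!is.null(s[[tag_key(0x0028, 0x0103)]]) &&
        s[[tag_key(0x0028, 0x0103)]] == 1)
      v[v >= 32768] <- v[v >= 32768] - 65536
    slope <- s[[tag_key(0x0028, 0x1053)]]
    icept <- s[[tag_key(0x0028, 0x1052)]]
    if (!is.null(slope)) v <- v * slope
    if (!is.null(icept)) v <- v + icept
    vox[, , k] <- v[seq_len(cols * rows)]
  }
  image_volume(vox, spacing = c(ps[2], ps[1], dz), origin = pos[1, ],
               orientation = cbind(dir_x, dir_y, normal))
}

# ---- habitat maps as DICOM segmentation objects ----------------------------

#' Export a habitat map as a DICOM segmentation object
#'
#' One binary segment per habitat label, bit-packed frames ordered
#' segment-major (all slices of habitat 1, then habitat 2, ...), sharing the
#' reference volume's frame of reference. The round trip through
#' [read_habitat_dicom()] reproduces the label array exactly.
#'
#' @param map a [habitat_map()].
#' @param reference the [image_volume()] the map is congruent with.
#' @param path output file path (.dcm).
#' @return Invisibly, `path`.
#' @export
write_habitat_dicom <- function(map, reference, path) {
  if (!inherits(map, "habitat_map")) stop("map must be a habitat_map")
  if (!inherits(reference, "image_volume"))
    stop("reference must be an image_volume")
  d <- dim(map$labels)
  if (!identical(d, dim(reference$voxels)))
    stop("habitat map and reference volume differ in shape")
  if (map$k == 0L) stop("empty habitat map")
  k <- map$k
  npix <- d[1] * d[2]
  frames <- vector("list", k * d[3])
  fi <- 1
  per_frame <- vector("list", k * d[3])
  for (s in seq_len(k)) {
    for (z in seq_len(d[3])) {
      bits <- as.integer(map$labels[, , z] == s)
      pad <- (-length(bits)) %% 8
      frames[[fi]] <- packBits(as.raw(c(bits, integer(pad))), type = "raw")
      per_frame[[fi]] <- list(
        "PlanePositionSequence" = voxel_to_patient(reference, c(1, 1, z)),
        "SegmentIdentificationSequence" = s
      )
      fi <- fi + 1
    }
  }
  pix <- do.call(c, frames)
  if (length(pix) %% 2 == 1) pix <- c(pix, as.raw(0))
  sop_uid <- new_uid(c(map$labels, reference$spacing, reference$origin))
  seg_items <- lapply(seq_len(k), function(s) list(
    dcm_element(0x0062, 0x0004, "US", s),                 # SegmentNumber
    dcm_element(0x0062, 0x0005, "LO", sprintf("habitat %d", s)),
    dcm_element(0x0062, 0x0001, "CS", "BINARY")
  ))
  shared <- list(list(
    dcm_element(0x0028, 0x9110, "SQ", list(list(        # PixelMeasures
      dcm_element(0x0028, 0x0030, "DS",
                  c(reference$spacing[2], reference$spacing[1])),
      dcm_element(0x0018, 0x0050, "DS", reference$spacing[3]),
      dcm_element(0x0018, 0x0088, "DS", reference$spacing[3])
    ))),
    dcm_element(0x0020, 0x9116, "SQ", list(list(        # PlaneOrientation
      dcm_element(0x0020, 0x0037, "DS",
                  c(reference$orientation[, 1], reference$orientation[, 2]))
    )))
  ))
  pf_items <- lapply(per_frame, function(f) list(
    dcm_element(0x0020, 0x9113, "SQ", list(list(        # PlanePosition
      dcm_element(0x0020, 0x0032, "DS", f$PlanePositionSequence)
    ))),
    dcm_element(0x0062, 0x000A, "SQ", list(list(        # SegmentIdentification
      dcm_element(0x0062, 0x000B, "US", f$SegmentIdentificationSequence)
    )))
  ))
  dataset <- list(
    dcm_element(0x0008, 0x0016, "UI", SOP_SEG),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "SEG"),
    dcm_element(0x0020, 0x000D, "UI", paste0(sop_uid, ".1")),
    dcm_element(0x0020, 0x000E, "UI", paste0(sop_uid, ".2")),
    dcm_element(0x0020, 0x0052, "UI", paste0(sop_uid, ".3")),
    dcm_element(0x0062, 0x0001, "CS", "BINARY"),
    dcm_element(0x0062, 0x0002, "SQ", seg_items),
    dcm_element(0x0028, 0x0002, "US", 1),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0008, "IS", k * d[3]),       # NumberOfFrames
    dcm_element(0x0028, 0x0010, "US", d[2]),           # Rows
    dcm_element(0x0028, 0x0011, "US", d[1]),           # Columns
    dcm_element(0x0028, 0x0100, "US", 1),
    dcm_element(0x0028, 0x0101, "US", 1),
    dcm_element(0x0028, 0x0102, "US", 0),
    dcm_element(0x0028, 0x0103, "US", 0),
    dcm_element(0x5200, 0x9229, "SQ", shared),
    dcm_element(0x5200, 0x9230, "SQ", pf_items),
    dcm_element(0x7FE0, 0x0010, "OB", pix)
  )
  write_dicom_file(path, SOP_SEG, sop_uid, dataset)
  invisible(path)
}

#' Read a habitat map from a DICOM segmentation object
#'
#' @param path a .dcm file written by [write_habitat_dicom()] (or a
#'   compatible explicit-VR-little-endian binary segmentation).
#' @return A [habitat_map()].
#' @export
read_habitat_dicom <- function(path) {
  ds <- read_dicom_file(path)
  if (!identical(ds[[tag_key(0x0008, 0x0016)]], SOP_SEG))
    stop("not a DICOM segmentation object")
  k <- length(ds[[tag_key(0x0062, 0x0002)]])
  nf <- ds[[tag_key(0x0028, 0x0008)]]
  rows <- ds[[tag_key(0x0028, 0x0010)]]
  cols <- ds[[tag_key(0x0028, 0x0011)]]
  if (k < 1 || nf %% k != 0)
    stop("inconsistent segment/frame counts")
  nz <- nf %/% k
  shared <- ds[[tag_key(0x5200, 0x9229)]][[1]]
  pm <- shared[[tag_key(0x0028, 0x9110)]][[1]]
  ps <- pm[[tag_key(0x0028, 0x0030)]]
  dz <- pm[[tag_key(0x0018, 0x0088)]]
  if (is.null(dz)) dz <- pm[[tag_key(0x0018, 0x0050)]]
  pix <- ds[[tag_key(0x7FE0, 0x0010)]]
  npix <- rows * cols
  frame_bytes <- ceiling(npix / 8)
  labels <- array(0L, dim = c(cols, rows, nz))
  fi <- 0
  # frame -> segment via per-frame identification when present, else order
  pf <- ds[[tag_key(0x5200, 0x9230)]]
  for (f in seq_len(nf)) {
    off <- (f - 1) * frame_bytes
    bytes <- pix[(off + 1):(off + frame_bytes)]
    bits <- as.integer(rawToBits(bytes))[seq_len(npix)]
    seg <- NA_integer_
    if (!is.null(pf) && length(pf) >= f) {
      sid <- pf[[f]][[tag_key(0x0062, 0x000A)]]
      if (!is.null(sid))
        seg <- as.integer(sid[[1]][[tag_key(0x0062, 0x000B)]])
    }
    if (is.na(seg)) seg <- ((f - 1) %/% nz) + 1L
    z <- ((f - 1) %% nz) + 1L
    sl <- labels[, , z]
    sl[bits == 1L] <- seg
    labels[, , z] <- sl
    fi <- fi + 1
  }
  habitat_map(labels, spacing = c(ps[2], ps[1], dz), k_max = max(labels))
}
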