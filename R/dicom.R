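# Minimal DICOM support, scoped to RT Plan objects in explicit VR little
# endian (transfer syntax 1.2.840.10008.1.2.1). This is not a general DICOM
# toolkit: it exists so plans can be ingested from the standard clinical
# export format and so synthetic plans can be written out for round-trip
# testing. Written files carry the RT Plan SOP class but are NOT
# treatment-deliverable.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"

# VRs encoded with a 2-byte reserved field and 4-byte length
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
STRING_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST",
                "TM", "UI", "UT", "UC", "UR")

uint16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

fmt_ds <- function(x) {
  s <- sprintf("%.8f", x)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  s
}

# Build one explicit-VR element as a raw vector. `value` is already raw.
dcm_element <- function(group, elem, vr, value) {
  stopifnot(length(value) %% 2 == 0)
  hdr <- c(uint16_raw(group), uint16_raw(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), uint32_raw(length(value)), value)
  } else {
    if (length(value) > 65534) stop("value too long for short VR")
    c(hdr, uint16_raw(length(value)), value)
  }
}

dcm_str <- function(group, elem, vr, values) {
  s <- paste(values, collapse = "\\")
  r <- charToRaw(s)
  if (length(r) %% 2 == 1)
    r <- c(r, if (vr == "UI") as.raw(0) else charToRaw(" "))
  dcm_element(group, elem, vr, r)
}

dcm_ds <- function(group, elem, values) {
  dcm_str(group, elem, "DS", vapply(values, fmt_ds, character(1)))
}

dcm_is <- function(group, elem, values) {
  dcm_str(group, elem, "IS", sprintf("%d", as.integer(values)))
}

# Sequence with defined lengths; items is a list of raw vectors (item bodies)
dcm_sq <- function(group, elem, items) {
  body <- raw(0)
  for (it in items)
    body <- c(body, uint16_raw(0xFFFE), uint16_raw(0xE000),
              uint32_raw(length(it)), it)
  dcm_element(group, elem, "SQ", body)
}

#' Write a plan as a (synthetic) DICOM RT Plan file
#'
#' Serializes a [vmat_plan()] to a minimal explicit-VR little-endian DICOM
#' RT Plan: beam sequence with per-control-point MLC and jaw positions,
#' fraction group with per-beam metersets, and a dose reference carrying the
#' prescription. The file is intended for interchange and testing only; it
#' omits most of the attributes a deliverable plan requires.
#'
#' @param plan A [vmat_plan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rtplan_dicom <- function(plan, path) {
  np <- plan$mlc$n_pairs
  beams <- lapply(seq_along(plan$arcs), function(ai) {
    arc <- plan$arcs[[ai]]
    bld <- dcm_sq(0x300A, 0x00B6, list(
      c(dcm_str(0x300A, 0x00B8, "CS", "ASYMX"),
        dcm_is(0x300A, 0x00BC, 1L)),
      c(dcm_str(0x300A, 0x00B8, "CS", "ASYMY"),
        dcm_is(0x300A, 0x00BC, 1L)),
      c(dcm_str(0x300A, 0x00B8, "CS", "MLCX"),
        dcm_is(0x300A, 0x00BC, np),
        dcm_ds(0x300A, 0x00BE, plan$mlc$leaf_bounds))
    ))
    cps <- lapply(seq_along(arc$control_points), function(ci) {
      cp <- arc$control_points[[ci]]
      pos <- dcm_sq(0x300A, 0x011A, list(
        c(dcm_str(0x300A, 0x00B8, "CS", "ASYMX"),
          dcm_ds(0x300A, 0x011C, cp$jaw_x)),
        c(dcm_str(0x300A, 0x00B8, "CS", "ASYMY"),
          dcm_ds(0x300A, 0x011C, cp$jaw_y)),
        c(dcm_str(0x300A, 0x00B8, "CS", "MLCX"),
          dcm_ds(0x300A, 0x011C, c(cp$bank_a, cp$bank_b)))
      ))
      c(dcm_is(0x300A, 0x0112, ci - 1L),
        dcm_ds(0x300A, 0x011E, cp$gantry_angle),
        dcm_str(0x300A, 0x011F, "CS",
                if (arc$gantry_direction == "CW") "CW" else "CC"),
        dcm_ds(0x300A, 0x0134, cp$cumulative_weight),
        pos)
    })
    c(dcm_is(0x300A, 0x00C0, ai),
      dcm_str(0x300A, 0x00C2, "LO", sprintf("Arc%d", ai)),
      dcm_str(0x300A, 0x00C4, "CS", "DYNAMIC"),
      bld,
      dcm_ds(0x300A, 0x010E, 1),
      dcm_is(0x300A, 0x0110, length(arc$control_points)),
      dcm_sq(0x300A, 0x0111, cps))
  })
  refbeams <- lapply(seq_along(plan$arcs), function(ai) {
    c(dcm_ds(0x300A, 0x0086, plan$arcs[[ai]]$beam_mu),
      dcm_is(0x300C, 0x0006, ai))
  })
  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", SOP_RTPLAN),
    dcm_str(0x0008, 0x0018, "UI", paste0("2.25.", format(1e8 + nchar(plan$plan_id)))),
    dcm_str(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_str(0x300A, 0x0002, "SH", substr(plan$plan_id, 1, 16)),
    dcm_str(0x300A, 0x0003, "LO", plan$plan_id),
    dcm_sq(0x300A, 0x0010, list(
      c(dcm_is(0x300A, 0x0012, 1L),
        dcm_ds(0x300A, 0x0026, plan$rx_dose_per_fraction * plan$n_fractions))
    )),
    dcm_sq(0x300A, 0x0070, list(
      c(dcm_is(0x300A, 0x0071, 1L),
        dcm_is(0x300A, 0x0078, plan$n_fractions),
        dcm_is(0x300A, 0x0080, length(plan$arcs)),
        dcm_sq(0x300C, 0x0004, refbeams))
    )),
    dcm_sq(0x300A, 0x00B0, beams)
  )
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", SOP_RTPLAN),
    dcm_str(0x0002, 0x0003, "UI", "2.25.100000001"),
    dcm_str(0x0002, 0x0010, "UI", TS_EXPLICIT_LE)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32_raw(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

## ---- reader ----

r_uint <- function(raw, pos, size) {
  if (size == 2L)
    return(readBin(raw[pos:(pos + 1L)], "integer", size = 2L,
                   endian = "little", signed = FALSE))
  # 4-byte reads are always signed in readBin; recover the unsigned value
  v <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v + 2^32 else v
}

parse_value <- function(vr, bytes) {
  if (vr %in% c("DS", "IS")) {
    s <- trimws(rawToChar(bytes))
    if (!nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, "\\\\")[[1]])
  } else if (vr %in% STRING_VRS) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    trimws(strsplit(s, "\\\\")[[1]])
  } else if (vr == "UL") {
    readBin(bytes, "integer", n = length(bytes) / 4, size = 4, endian = "little")
  } else if (vr == "US") {
    readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
            endian = "little", signed = FALSE)
  } else if (vr %in% c("FL", "FD")) {
    readBin(bytes, "double", n = length(bytes) / ifelse(vr == "FL", 4, 8),
            size = ifelse(vr == "FL", 4, 8), endian = "little")
  } else bytes
}

# Parse an explicit-VR dataset between byte offsets [pos, end]; returns
# list(elements = named list by "GGGGEEEE", pos = next offset).
parse_dataset <- function(raw, pos, end) {
  out <- list()
  while (pos <= end - 7L) {
    group <- r_uint(raw, pos, 2L); elem <- r_uint(raw, pos + 2L, 2L)
    if (group == 0xFFFE && elem == 0xE00D) {  # item delimiter
      pos <- pos + 8L
      return(list(elements = out, pos = pos, delimited = TRUE))
    }
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- r_uint(raw, pos + 8L, 4L); body <- pos + 12L
    } else {
      len <- r_uint(raw, pos + 6L, 2L); body <- pos + 8L
    }
    tag <- sprintf("%04X%04X", group, elem)
    if (vr == "SQ") {
      sq_end <- if (len == 4294967295) end else body + len - 1L
      items <- list()
      p <- body
      repeat {
        if (p > sq_end - 7L) break
        g <- r_uint(raw, p, 2L); e <- r_uint(raw, p + 2L, 2L)
        if (g == 0xFFFE && e == 0xE0DD) { p <- p + 8L; break }
        if (!(g == 0xFFFE && e == 0xE000)) stop("malformed sequence item tag")
        ilen <- r_uint(raw, p + 4L, 4L)
        if (ilen == 4294967295) {
          r <- parse_dataset(raw, p + 8L, sq_end)
          items[[length(items) + 1L]] <- r$elements
          p <- r$pos
        } else {
          r <- parse_dataset(raw, p + 8L, p + 8L + ilen - 1L)
          items[[length(items) + 1L]] <- r$elements
          p <- p + 8L + ilen
        }
      }
      out[[tag]] <- items
      pos <- p
    } else {
      out[[tag]] <- parse_value(vr, if (len > 0) raw[body:(body + len - 1L)] else raw(0))
      pos <- body + len
    }
  }
  list(elements = out, pos = pos, delimited = FALSE)
}

dget <- function(el, tag, default = NULL) {
  if (!is.null(el[[tag]])) el[[tag]] else default
}

#' Read a DICOM RT Plan file into a VMAT plan
#'
#' Parses an explicit-VR little-endian DICOM RT Plan and maps every dynamic
#' beam carrying MLC position sequences to a [vmat_arc()]. Leaf positions
#' are taken as mm at isocenter (bank A then bank B in the `MLCX` position
#' sequence); cumulative meterset weights are normalized to `[0, 1]` using
#' the beam's final cumulative meterset weight; jaw positions and gantry
#' angles are carried forward across control points where the file omits
#' them, as the standard allows.
#'
#' @param path Path to a DICOM RT Plan file.
#' @return A [vmat_plan()].
#' @export
read_rtplan <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  # file meta group: first element must be (0002,0000) UL group length
  if (r_uint(raw, 133L, 2L) != 0x0002 || r_uint(raw, 135L, 2L) != 0x0000)
    stop("missing file meta group length")
  meta_len <- r_uint(raw, 141L, 4L)
  ds_start <- 133L + 12L + meta_len  # (0002,0000) UL element is 12 bytes
  meta <- parse_dataset(raw, 133L, ds_start - 1L)
  ts <- dget(meta$elements, "00020010")
  if (!identical(ts, TS_EXPLICIT_LE))
    stop("unsupported transfer syntax: ", ts)
  ds <- parse_dataset(raw, ds_start, length(raw))$elements
  modality <- dget(ds, "00080060", "")
  if (!identical(modality, "RTPLAN"))
    stop("not an RT Plan (Modality = '", modality, "')")
  beams <- dget(ds, "300A00B0")
  if (is.null(beams) || !length(beams)) stop("RT Plan has no BeamSequence")

  # per-beam metersets from the fraction group
  mu_by_beam <- list(); n_fx <- 1L
  fg <- dget(ds, "300A0070")
  if (!is.null(fg) && length(fg)) {
    n_fx <- as.integer(dget(fg[[1]], "300A0078", 1))
    for (rb in dget(fg[[1]], "300C0004", list())) {
      bn <- as.integer(dget(rb, "300C0006", NA))
      mu_by_beam[[as.character(bn)]] <- dget(rb, "300A0086", NA_real_)
    }
  }
  rx_total <- NA_real_
  dr <- dget(ds, "300A0010")
  if (!is.null(dr) && length(dr)) rx_total <- dget(dr[[1]], "300A0026", NA_real_)
  if (is.na(rx_total)) stop("RT Plan carries no target prescription dose")

  mlc <- NULL
  arcs <- list()
  for (bi in seq_along(beams)) {
    b <- beams[[bi]]
    bnum <- as.integer(dget(b, "300A00C0", bi))
    bname <- dget(b, "300A00C2", sprintf("beam %d", bnum))
    bld <- dget(b, "300A00B6", list())
    np <- NULL; bounds <- NULL
    for (d in bld) {
      if (identical(dget(d, "300A00B8"), "MLCX")) {
        np <- as.integer(dget(d, "300A00BC"))
        bounds <- dget(d, "300A00BE")
      }
    }
    cpseq <- dget(b, "300A0111", list())
    has_mlc <- !is.null(np) &&
      any(vapply(cpseq, function(cp) {
        any(vapply(dget(cp, "300A011A", list()),
                   function(d) identical(dget(d, "300A00B8"), "MLCX"), logical(1)))
      }, logical(1)))
    if (!has_mlc)
      stop(sprintf("beam '%s' (number %d) has no MLC position sequence", bname, bnum))
    if (is.null(mlc)) {
      widths <- diff(bounds)
      mlc <- structure(list(n_pairs = np, leaf_widths = widths,
                            leaf_bounds = bounds), class = "mlc_geometry")
    }
    final_w <- dget(b, "300A010E", 1)
    gantry <- NA_real_; direction <- "CW"
    jaw_x <- c(-200, 200); jaw_y <- c(-200, 200)
    bank_a <- rep(0, np); bank_b <- rep(0, np)
    cps <- list(); weights <- numeric(0)
    for (cp in cpseq) {
      g <- dget(cp, "300A011E"); if (!is.null(g)) gantry <- g
      dirs <- dget(cp, "300A011F")
      if (!is.null(dirs) && dirs %in% c("CW", "CC"))
        direction <- if (dirs == "CC") "CCW" else "CW"
      for (d in dget(cp, "300A011A", list())) {
        ty <- dget(d, "300A00B8"); pos <- dget(d, "300A011C")
        if (identical(ty, "MLCX")) {
          if (length(pos) != 2 * np)
            stop("MLCX position count ", length(pos), " != 2 * ", np)
          bank_a <- pos[seq_len(np)]; bank_b <- pos[np + seq_len(np)]
        } else if (ty %in% c("X", "ASYMX")) jaw_x <- pos
        else if (ty %in% c("Y", "ASYMY")) jaw_y <- pos
      }
      w <- dget(cp, "300A0134", NA_real_)
      weights <- c(weights, w)
      cps[[length(cps) + 1L]] <- control_point(gantry, w, bank_a, bank_b,
                                               jaw_x, jaw_y)
    }
    if (any(is.na(weights)))
      stop(sprintf("beam '%s': missing cumulative meterset weight", bname))
    if (any(diff(weights) < -1e-12))
      stop(sprintf("beam '%s': non-monotone cumulative meterset weight", bname))
    if (final_w > 0 && abs(final_w - 1) > 1e-12)
      for (i in seq_along(cps))
        cps[[i]]$cumulative_weight <- cps[[i]]$cumulative_weight / final_w
    angles <- vapply(cps, function(cp) cp$gantry_angle, numeric(1))
    spacing <- if (length(angles) > 1)
      stats::median(abs(gantry_delta(angles[-length(angles)], angles[-1]))) else 0
    mu <- mu_by_beam[[as.character(bnum)]]
    if (is.null(mu) || is.na(mu)) mu <- 0
    arcs[[length(arcs) + 1L]] <- vmat_arc(cps, mu, direction, spacing)
  }
  plan_id <- dget(ds, "300A0003", dget(ds, "300A0002", "rtplan"))
  vmat_plan(plan_id, arcs, rx_total / n_fx, n_fx, mlc)
}
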