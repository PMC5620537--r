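#' Create a provenance notebook
#'
#' The spectral notebook holds annotated, self-contained evidence items:
#' peak lists (raw or processed, with their processing records), extracted
#' ion chromatograms and results excerpts, each with drawing/text
#' annotations and attached scripts or search parameters. A saved bundle
#' renders and replays with zero access to any raw run file.
#'
#' @return An empty `mz_notebook`.
#' @export
notebook <- function() {
  structure(list(entries = list(), next_id = 1L), class = "mz_notebook")
}

#' @export
print.mz_notebook <- function(x, ...) {
  cat(sprintf("<mz_notebook> %d entr%s\n", length(x$entries),
              if (length(x$entries) == 1) "y" else "ies"))
  for (e in x$entries) {
    cat(sprintf("  [%d] %s (%s; %d annotation(s), %d attachment(s))\n",
                e$id, e$title, e$type, length(e$annotations), length(e$attachments)))
  }
  invisible(x)
}

item_type <- function(item) {
  if (inherits(item, "mz_spectrum")) "spectrum"
  else if (inherits(item, "mz_chromatogram")) "chromatogram"
  else if (is.data.frame(item)) "results"
  else abort("item must be a spectrum, chromatogram, or results data frame")
}

nb_timestamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

#' Add an evidence item to a notebook
#'
#' @param nb An `mz_notebook`.
#' @param item An `mz_spectrum`, `mz_chromatogram`, or results data frame.
#' @param title Entry title.
#' @param record Optional `processing_record` when `item` is a processed
#'   spectrum (embedded so the transformation replays inside the bundle).
#' @return The notebook with the entry appended (its id is `nb$next_id - 1`).
#' @export
nb_add_entry <- function(nb, item, title, record = NULL) {
  stopifnot(inherits(nb, "mz_notebook"))
  entry <- list(
    id = nb$next_id, title = title, type = item_type(item),
    item = item, record = record,
    annotations = list(), attachments = list(),
    created = nb_timestamp(), modified = nb_timestamp()
  )
  nb$entries[[length(nb$entries) + 1L]] <- entry
  nb$next_id <- nb$next_id + 1L
  nb
}

entry_index <- function(nb, entry_id) {
  ids <- vapply(nb$entries, function(e) e$id, integer(1))
  i <- match(entry_id, ids)
  if (is.na(i)) abort(paste0("no notebook entry with id ", entry_id))
  i
}

#' @rdname nb_add_entry
#' @param entry_id Target entry id.
#' @export
nb_entry <- function(nb, entry_id) nb$entries[[entry_index(nb, entry_id)]]

anchor_range <- function(entry) {
  if (entry$type == "spectrum") {
    p <- entry$item$peaks
    list(x = range(p$mz), y = c(0, max(p$intensity, 0)))
  } else if (entry$type == "chromatogram") {
    list(x = range(entry$item$rt), y = c(0, max(entry$item$intensity, 0)))
  } else {
    NULL  # results excerpts anchor by row, not data coordinates
  }
}

#' Annotate a notebook entry
#'
#' Annotations anchor in data coordinates (m/z or rt on x, intensity on y),
#' not canvas pixels, so they survive re-rendering at any size. Anchors must
#' lie within the item's data range.
#'
#' @param nb An `mz_notebook`.
#' @param entry_id Target entry id.
#' @param kind One of `"text"`, `"arrow"`, `"bracket"`, `"highlight-region"`.
#' @param x,y Anchor in data coordinates. For region/bracket kinds `x` may be
#'   length 2.
#' @param text Label text (for `"text"` and `"arrow"`).
#' @return The updated notebook.
#' @export
nb_annotate <- function(nb, entry_id, kind, x, y = 0, text = "") {
  kind <- match.arg(kind, c("text", "arrow", "bracket", "highlight-region"))
  i <- entry_index(nb, entry_id)
  entry <- nb$entries[[i]]
  rng <- anchor_range(entry)
  if (!is.null(rng)) {
    if (any(x < rng$x[1] - 1e-9) || any(x > rng$x[2] + 1e-9)) {
      abort(sprintf("annotation anchor x outside data range [%g, %g]",
                    rng$x[1], rng$x[2]))
    }
    if (any(y < rng$y[1] - 1e-9) || any(y > rng$y[2] + 1e-9)) {
      abort(sprintf("annotation anchor y outside data range [%g, %g]",
                    rng$y[1], rng$y[2]))
    }
  }
  entry$annotations[[length(entry$annotations) + 1L]] <-
    list(kind = kind, x = x, y = y, text = text)
  entry$modified <- nb_timestamp()
  nb$entries[[i]] <- entry
  nb
}

#' Attach scripts, parameters or notes to an entry
#'
#' @param nb An `mz_notebook`.
#' @param entry_id Target entry id.
#' @param kind One of `"script"`, `"search_parameters"`, `"notes"`.
#' @param payload Character scalar (script text, notes) or named list
#'   (parameters).
#' @return The updated notebook.
#' @export
nb_attach <- function(nb, entry_id, kind, payload) {
  kind <- match.arg(kind, c("script", "search_parameters", "notes"))
  i <- entry_index(nb, entry_id)
  nb$entries[[i]]$attachments[[kind]] <- payload
  nb$entries[[i]]$modified <- nb_timestamp()
  nb
}

# ---- serialization ---------------------------------------------------------

spectrum_to_list <- function(s) {
  list(scan_id = s$scan_id, ms_level = s$ms_level, rt = s$rt,
       mz = s$peaks$mz, intensity = s$peaks$intensity,
       charge = s$peaks$charge,
       precursor_mz = s$precursor_mz, precursor_charge = s$precursor_charge,
       activation = s$activation, centroided = s$centroided)
}

json_int <- function(v) {
  if (is.null(v) || identical(v, "NA") || (length(v) == 1 && is.na(v))) NA_integer_
  else as.integer(v)
}

spectrum_from_list <- function(l) {
  n <- length(l$mz)
  chg <- if (is.null(l$charge)) rep(NA_integer_, n) else
    vapply(l$charge, json_int, integer(1))
  spectrum(l$scan_id, l$ms_level, l$rt,
           tibble(mz = as.numeric(unlist(l$mz)),
                  intensity = as.numeric(unlist(l$intensity)),
                  charge = chg),
           precursor_mz = l$precursor_mz,
           precursor_charge = json_int(l$precursor_charge),
           activation = l$activation, centroided = l$centroided)
}

entry_payload <- function(entry) {
  item <- switch(entry$type,
    spectrum = spectrum_to_list(entry$item),
    chromatogram = list(rt = entry$item$rt, intensity = entry$item$intensity,
                        query_mz = attr(entry$item, "query_mz"),
                        tol = attr(entry$item, "tol"),
                        tol_unit = attr(entry$item, "tol_unit")),
    results = as.list(as.data.frame(entry$item))
  )
  list(title = entry$title, type = entry$type, item = item,
       record = if (is.null(entry$record)) NULL else unclass(entry$record),
       annotations = entry$annotations, attachments = entry$attachments)
}

payload_json <- function(payload) {
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

entry_digest <- function(entry) sha256_of(payload_json(entry_payload(entry)))

#' Save / load a notebook bundle
#'
#' The bundle is one structured JSON document: a manifest of per-entry
#' sha256 digests followed by the entries themselves, every item embedded in
#' full — no external file references are needed to render or replay it.
#' On load each entry's digest is recomputed; mismatches (tampering,
#' corruption) are reported per entry via the `tampered` field and a warning.
#'
#' @param nb An `mz_notebook`.
#' @param path Bundle path (`.json`).
#' @return `save_bundle`: `path`, invisibly. `load_bundle`: the notebook;
#'   entries failing digest verification carry `tampered = TRUE`.
#' @export
save_bundle <- function(nb, path) {
  stopifnot(inherits(nb, "mz_notebook"))
  entries <- purrr::map(nb$entries, function(e) {
    list(id = e$id, created = e$created, modified = e$modified,
         digest = entry_digest(e), payload = entry_payload(e))
  })
  doc <- list(
    format = "mzcanvas-notebook-bundle", version = 1L,
    manifest = purrr::map(entries, function(e) list(id = e$id, digest = e$digest)),
    entries = entries
  )
  write_atomic(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                             null = "null", pretty = TRUE)), path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "mzc_data_error")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "mzcanvas-notebook-bundle")) {
    abort("not an mzcanvas notebook bundle", class = "mzc_data_error")
  }
  nb <- notebook()
  bad <- integer()
  for (e in doc$entries) {
    pl <- e$payload
    item <- switch(pl$type,
      spectrum = spectrum_from_list(pl$item),
      chromatogram = {
        ch <- tibble(rt = as.numeric(unlist(pl$item$rt)),
                     intensity = as.numeric(unlist(pl$item$intensity)))
        structure(ch, class = c("mz_chromatogram", class(ch)),
                  query_mz = pl$item$query_mz, tol = pl$item$tol,
                  tol_unit = pl$item$tol_unit)
      },
      results = as_tibble(purrr::map(pl$item, unlist))
    )
    record <- if (!is.null(pl$record)) {
      structure(pl$record, class = "processing_record")
    }
    entry <- list(
      id = e$id, title = pl$title, type = pl$type, item = item,
      record = record,
      annotations = purrr::map(pl$annotations, function(a) {
        a$x <- as.numeric(unlist(a$x)); a$y <- as.numeric(unlist(a$y)); a
      }),
      attachments = pl$attachments,
      created = e$created, modified = e$modified
    )
    recomputed <- entry_digest(entry)
    entry$tampered <- !identical(recomputed, e$digest)
    if (entry$tampered) bad <- c(bad, e$id)
    nb$entries[[length(nb$entries) + 1L]] <- entry
    nb$next_id <- max(nb$next_id, e$id + 1L)
  }
  if (length(bad)) {
    warn(paste0("digest mismatch (tampered or corrupt) in entry id(s): ",
                paste(bad, collapse = ", ")))
  }
  nb
}

# ---- graphics export -------------------------------------------------------

svg_num <- function(x) sprintf("%.2f", x)

render_entry_svg <- function(entry, width = 800, height = 400) {
  rng <- anchor_range(entry)
  if (is.null(rng)) abort("results excerpts cannot be rendered as graphics")
  pad <- 40
  xr <- rng$x; yr <- rng$y
  if (diff(xr) == 0) xr <- xr + c(-1, 1)
  if (diff(yr) == 0) yr <- yr + c(0, 1)
  sx <- function(x) pad + (x - xr[1]) / diff(xr) * (width - 2 * pad)
  sy <- function(y) (height - pad) - (y - yr[1]) / diff(yr) * (height - 2 * pad)
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<title>%s</title>', entry$title),
    sprintf('<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
            svg_num(pad), svg_num(height - pad), svg_num(width - pad), svg_num(height - pad))
  )
  if (entry$type == "spectrum") {
    p <- entry$item$peaks
    out <- c(out, sprintf(
      '<line class="peak" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
      svg_num(sx(p$mz)), svg_num(sy(0)), svg_num(sx(p$mz)), svg_num(sy(p$intensity))))
  } else {
    pts <- paste(sprintf("%s,%s", svg_num(sx(entry$item$rt)),
                         svg_num(sy(entry$item$intensity))), collapse = " ")
    out <- c(out, sprintf('<polyline class="trace" points="%s" fill="none" stroke="black"/>', pts))
  }
  for (a in entry$annotations) {
    if (a$kind == "text") {
      out <- c(out, sprintf('<text class="annotation" x="%s" y="%s">%s</text>',
                            svg_num(sx(a$x[1])), svg_num(sy(a$y[1])), a$text))
    } else if (a$kind == "arrow") {
      out <- c(out, sprintf(
        '<path class="annotation" d="M %s %s L %s %s" stroke="red" fill="none"/><text class="annotation" x="%s" y="%s">%s</text>',
        svg_num(sx(a$x[1])), svg_num(sy(a$y[1]) - 30), svg_num(sx(a$x[1])), svg_num(sy(a$y[1])),
        svg_num(sx(a$x[1])), svg_num(sy(a$y[1]) - 35), a$text))
    } else if (a$kind == "bracket") {
      x1 <- sx(min(a$x)); x2 <- sx(max(a$x)); yy <- sy(a$y[1])
      out <- c(out, sprintf(
        '<path class="annotation" d="M %s %s L %s %s L %s %s L %s %s" stroke="blue" fill="none"/>',
        svg_num(x1), svg_num(yy - 10), svg_num(x1), svg_num(yy - 20),
        svg_num(x2), svg_num(yy - 20), svg_num(x2), svg_num(yy - 10)))
    } else if (a$kind == "highlight-region") {
      x1 <- sx(min(a$x)); x2 <- sx(max(a$x))
      out <- c(out, sprintf(
        '<rect class="annotation" x="%s" y="%s" width="%s" height="%s" fill="yellow" fill-opacity="0.3"/>',
        svg_num(x1), svg_num(pad), svg_num(x2 - x1), svg_num(height - 2 * pad)))
    }
  }
  c(out, "</svg>")
}

#' Export a notebook entry as a graphic
#'
#' Spectra render as stick plots, chromatograms as line traces, with all
#' annotations drawn in data coordinates. SVG output is generated directly
#' (deterministic: identical entries give byte-identical files); PNG and PDF
#' go through the corresponding graphics device. `.ppt` is not supported.
#'
#' @param entry A notebook entry (from [nb_entry()]).
#' @param path Output file path.
#' @param format `"svg"`, `"png"`, or `"pdf"`.
#' @param width,height Canvas size in pixels (SVG/PNG) or inches x 100 (PDF).
#' @return `path`, invisibly.
#' @export
export_graphic <- function(entry, path, format = c("svg", "png", "pdf"),
                           width = 800, height = 400) {
  if (identical(format, "ppt") || (length(format) == 1 && !format %in% c("svg", "png", "pdf"))) {
    abort(paste0("unsupported graphic format: ", format), class = "mzc_data_error")
  }
  format <- match.arg(format)
  if (format == "svg") {
    return(write_atomic(render_entry_svg(entry, width, height), path))
  }
  if (format == "png") {
    grDevices::png(path, width = width, height = height, type = "cairo")
  } else {
    grDevices::pdf(path, width = width / 100, height = height / 100)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  if (entry$type == "spectrum") {
    p <- entry$item$peaks
    graphics::plot(p$mz, p$intensity, type = "h", xlab = "m/z (Th)",
                   ylab = "intensity", main = entry$title)
  } else if (entry$type == "chromatogram") {
    graphics::plot(entry$item$rt, entry$item$intensity, type = "l",
                   xlab = "rt (min)", ylab = "intensity", main = entry$title)
  } else {
    abort("results excerpts cannot be rendered as graphics")
  }
  for (a in entry$annotations) {
    if (a$kind %in% c("text", "arrow")) {
      graphics::text(a$x[1], a$y[1], a$text, pos = 3, col = "red")
    }
  }
  invisible(path)
}

#' Export an entry's peak list as an MSP library record
#'
#' NIST-compatible MSP text (`Name`, `PrecursorMZ`, `Charge`, `Num peaks`,
#' then `mz intensity` lines). For processed-spectrum entries the processed
#' peaks are exported, matching the embedded processing record's output.
#'
#' @param entry A notebook entry holding a spectrum.
#' @param path Output `.msp` path.
#' @return `path`, invisibly.
#' @export
export_peaklist <- function(entry, path) {
  if (entry$type != "spectrum") {
    abort("export_peaklist needs a spectrum entry", class = "mzc_data_error")
  }
  s <- entry$item
  lines <- c(
    paste0("Name: ", entry$title),
    if (!is.null(s$precursor_mz)) sprintf("PrecursorMZ: %.6f", s$precursor_mz),
    if (!is.na(s$precursor_charge)) sprintf("Charge: %d", s$precursor_charge),
    sprintf("Num peaks: %d", nrow(s$peaks)),
    sprintf("%.6f %.4f", s$peaks$mz, s$peaks$intensity),
    ""
  )
  write_atomic(lines, path)
}

#' Read an MSP library record (round-trip utility)
#'
#' @param path MSP file path.
#' @return A list per record: `name`, `precursor_mz`, `charge`, `peaks`.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  starts <- grep("^Name: ", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  purrr::map2(starts, ends, function(a, b) {
    body <- lines[a:b]
    getv <- function(key) {
      m <- grep(paste0("^", key, ": "), body, value = TRUE)
      if (length(m)) sub(paste0("^", key, ": "), "", m[1]) else NA_character_
    }
    np_line <- grep("^Num peaks: ", body)
    npk <- as.integer(sub("^Num peaks: ", "", body[np_line]))
    pk <- body[(np_line + 1):(np_line + npk)]
    pm <- do.call(rbind, strsplit(trimws(pk), "[ \t]+"))
    list(name = getv("Name"),
         precursor_mz = as.numeric(getv("PrecursorMZ")),
         charge = as.integer(getv("Charge")),
         peaks = tibble(mz = as.numeric(pm[, 1]), intensity = as.numeric(pm[, 2])))
  })
}
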