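#' @section Spectral library:
#' Each group of correlated bins represents the ions of one metabolite
#' and becomes a library entry: the averages of mass, area, RI and RT of
#' every member bin, the inferred monomer mass and ion-form labels, and
#' (for LC/MS-MS data) the MS2 sub-spectra assembled per primary ion.
#' Query groups are matched against the library by an RI-gated cosine
#' similarity; groups matching nothing are registered as numbered
#' unknowns so they can be tracked in future studies.
#' @name spectral-library
NULL

#' Assemble the MS2 sub-spectrum of a primary ion bin
#'
#' MS2 peaks whose precursor mass lies within the mass window of the
#' primary bin's center are retrieved from the bin's singlet samples
#' only, and binned along the mass axis (greedy, descending area, no RI
#' dimension). Fragment bins with fewer than `min_correlated_ions`
#' singlets are dropped; the bin with the maximal mean intensity becomes
#' the normalize bin (relative intensity 100), and fragments below
#' `min_rel_intensity_pct` of it are dropped.
#'
#' @param primary_bin_id id of a primary (MS1) bin in `b`.
#' @param b a `ps_binning` with statistics.
#' @param s the `ps_sample_set` holding the study's MS2 peaks.
#' @param t a [ps_thresholds()] object.
#' @return A `ps_ms2_spectrum`: precursor info plus a fragment table
#'   (`mean_mz`, `mean_intensity`, `relative_intensity_pct`,
#'   `n_singlets`). An empty fragment table is valid (e.g. GC/EI data).
#' @export
bin_secondary_ions <- function(primary_bin_id, b, s, t = ps_thresholds()) {
  bin <- b$bins[b$bins$bin_id == primary_bin_id, ]
  stopifnot(nrow(bin) == 1)
  sing_samples <- b$peaks$sample_id[b$peaks$bin_id == primary_bin_id &
                                      b$peaks$is_singlet]
  ms2 <- s$peaks[s$peaks$ms_level == 2L &
                   s$peaks$sample_id %in% sing_samples &
                   abs(s$peaks$precursor_mz - bin$center_mz) <=
                     t$mass_window, , drop = FALSE]
  empty <- data.frame(mean_mz = numeric(0), mean_intensity = numeric(0),
                      relative_intensity_pct = numeric(0),
                      n_singlets = integer(0))
  out <- structure(list(precursor_bin_id = primary_bin_id,
                        precursor_mz = bin$center_mz, fragments = empty),
                   class = "ps_ms2_spectrum")
  if (nrow(ms2) == 0) return(out)
  # 1-D greedy binning along m/z, descending area
  ord <- order(-ms2$area, ms2$mz, ms2$peak_id)
  centers <- numeric(0)
  assign <- integer(nrow(ms2))
  for (i in ord) {
    d <- abs(ms2$mz[i] - centers)
    hit <- which(d <= t$mass_window)
    if (length(hit)) {
      assign[i] <- hit[which.min(d[hit])]
    } else {
      centers <- c(centers, ms2$mz[i])
      assign[i] <- length(centers)
    }
  }
  key <- paste(assign, ms2$sample_id, sep = "\r")
  singlet <- !(key %in% key[duplicated(key)])
  sing <- ms2[singlet, , drop = FALSE]
  sbin <- assign[singlet]
  if (nrow(sing) == 0) return(out)
  grp <- factor(sbin, levels = seq_along(centers))
  frag <- data.frame(
    mean_mz = as.numeric(tapply(sing$mz, grp, mean)),
    mean_intensity = as.numeric(tapply(sing$area, grp, mean)),
    n_singlets = as.integer(table(grp))
  )
  frag <- frag[frag$n_singlets >= t$min_correlated_ions, , drop = FALSE]
  if (nrow(frag) == 0) return(out)
  top <- max(frag$mean_intensity)
  frag$relative_intensity_pct <- 100 * frag$mean_intensity / top
  frag <- frag[frag$relative_intensity_pct >= t$min_rel_intensity_pct, ,
               drop = FALSE]
  frag <- frag[order(-frag$mean_intensity), , drop = FALSE]
  rownames(frag) <- NULL
  out$fragments <- frag[c("mean_mz", "mean_intensity",
                          "relative_intensity_pct", "n_singlets")]
  out
}

#' Build a library entry from a bin group
#'
#' One ion per member bin, carrying the averages of mass, RI and RT over
#' the bin's singlets and the area relative to the group's normalizer
#' (normalizer = 100). The inferred monomer mass, ion form labels, and
#' any MS2 sub-spectra are attached, along with provenance (study id,
#' sample count, creation thresholds).
#'
#' @param g a `ps_groups` (ideally after [infer_monomers()] and
#'   annotation).
#' @param group_id which group to convert.
#' @param s the `ps_sample_set` (for MS2 retrieval); may be `NULL` to
#'   skip MS2 assembly.
#' @param t a [ps_thresholds()] object.
#' @param name entry name; `NULL` leaves the entry unnamed (to be filled
#'   by matching or unknown registration).
#' @param study_id provenance tag.
#' @return A `ps_library_entry`.
#' @export
build_library_entry <- function(g, group_id, s = NULL, t = ps_thresholds(),
                                name = NULL, study_id = "study") {
  members <- g$bins[!is.na(g$bins$group_id) & g$bins$group_id == group_id, ,
                    drop = FALSE]
  if (nrow(members) == 0) stop("group ", group_id, " has no member bins")
  members <- members[order(-members$mean_area), , drop = FALSE]
  norm_area <- members$mean_area[1]
  ions <- data.frame(
    mean_mz = members$mean_mz,
    mean_ri = members$mean_ri,
    mean_rt = members$mean_rt,
    relative_area_pct = 100 * members$mean_area / norm_area,
    form_label = ifelse(is.na(members$form_label), "unassigned",
                        members$form_label)
  )
  mono <- if (!is.null(g$monomers)) {
    g$monomers$monomer_mz[g$monomers$group_id == group_id]
  } else NA_real_
  if (!length(mono)) mono <- NA_real_
  ms2 <- list()
  if (!is.null(s) && any(s$peaks$ms_level == 2L)) {
    for (bid in members$bin_id) {
      sp <- bin_secondary_ions(bid, g$binning, s, t)
      if (nrow(sp$fragments) > 0) ms2[[length(ms2) + 1L]] <- sp
    }
  }
  structure(
    list(entry_id = NA_character_,
         name = name,
         ions = ions,
         monomer_mz = mono,
         ms2 = ms2,
         provenance = list(study_id = study_id,
                           n_samples = length(g$binning$samples),
                           thresholds = unclass(t))),
    class = "ps_library_entry"
  )
}

#' Create an empty spectral library
#'
#' @return A `ps_library` with no entries.
#' @export
new_library <- function() {
  structure(list(version = 1L, next_unknown = 1L, entries = list()),
            class = "ps_library")
}

#' Add an entry to a library
#'
#' @param lib a `ps_library`.
#' @param entry a `ps_library_entry`; gets an auto-assigned `entry_id`.
#' @return The updated library.
#' @export
add_entry <- function(lib, entry) {
  entry$entry_id <- sprintf("E%04d", length(lib$entries) + 1L)
  if (is.null(entry$name)) entry$name <- entry$entry_id
  lib$entries[[entry$entry_id]] <- entry
  lib
}

#' Persist / load a library as JSON
#'
#' Full-fidelity, versioned representation; the inverse of each other.
#'
#' @param lib a `ps_library`.
#' @param path file path.
#' @return `read_library` returns the `ps_library`.
#' @export
write_library <- function(lib, path) {
  raw <- unclass(lib)
  raw$entries <- lapply(raw$entries, function(e) {
    e <- unclass(e)
    e$ms2 <- lapply(e$ms2, unclass)
    e
  })
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (is.null(raw$version)) stop("not a spectral library file: ", path)
  entries <- lapply(raw$entries, function(e) {
    e$ions <- as.data.frame(e$ions)
    e$monomer_mz <- if (is.null(e$monomer_mz)) NA_real_ else e$monomer_mz
    e$ms2 <- lapply(if (is.null(e$ms2)) list() else e$ms2, function(sp) {
      sp$fragments <- as.data.frame(sp$fragments)
      class(sp) <- "ps_ms2_spectrum"
      sp
    })
    class(e) <- "ps_library_entry"
    e
  })
  structure(list(version = raw$version, next_unknown = raw$next_unknown,
                 entries = entries),
            class = "ps_library")
}

#' Export / import a library in MSP text format
#'
#' Writes one `NAME:` block per entry with the entry RI, a `Comments:`
#' line carrying the monomer mass and ion form labels, `Num Peaks:` and
#' mass/relative-area pairs, for interoperability with spectral tools.
#' Masses are written to 4 decimals and relative areas to 2 decimals;
#' the reader restores entries at that precision (MS2 sub-spectra and
#' provenance are not representable in MSP and are dropped).
#'
#' @param lib a `ps_library`.
#' @param path file path.
#' @return `read_msp` returns a `ps_library`.
#' @export
write_msp <- function(lib, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (e in lib$entries) {
    writeLines(sprintf("NAME: %s", e$name), con)
    writeLines(sprintf("RI: %.1f", e$ions$mean_ri[1]), con)
    comment <- if (is.finite(e$monomer_mz)) {
      sprintf("Comments: monomer_mz=%.4f forms=%s", e$monomer_mz,
              paste(e$ions$form_label, collapse = ";"))
    } else {
      sprintf("Comments: forms=%s", paste(e$ions$form_label, collapse = ";"))
    }
    writeLines(comment, con)
    writeLines(sprintf("Num Peaks: %d", nrow(e$ions)), con)
    writeLines(sprintf("%.4f %.2f", e$ions$mean_mz,
                       e$ions$relative_area_pct), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_msp
#' @export
read_msp <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lib <- new_library()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^NAME:", lines[i])) { i <- i + 1; next }
    name <- sub("^NAME:\\s*", "", lines[i])
    ri <- NA_real_
    mono <- NA_real_
    forms <- character(0)
    i <- i + 1
    while (i <= length(lines) && !grepl("^Num Peaks:", lines[i])) {
      if (grepl("^RI:", lines[i])) {
        ri <- as.numeric(sub("^RI:\\s*", "", lines[i]))
      }
      if (grepl("^Comments:", lines[i])) {
        if (grepl("monomer_mz=", lines[i])) {
          mono <- as.numeric(sub(".*monomer_mz=([0-9.]+).*", "\\1", lines[i]))
        }
        if (grepl("forms=", lines[i])) {
          forms <- strsplit(sub(".*forms=", "", lines[i]), ";")[[1]]
        }
      }
      i <- i + 1
    }
    n <- as.integer(sub("^Num Peaks:\\s*", "", lines[i]))
    pk <- do.call(rbind, lapply(lines[i + seq_len(n)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    i <- i + n + 1
    ions <- data.frame(
      mean_mz = pk[, 1], mean_ri = ri, mean_rt = NA_real_,
      relative_area_pct = pk[, 2],
      form_label = if (length(forms) == n) forms else
        rep("unassigned", n))
    entry <- structure(
      list(entry_id = NA_character_, name = name, ions = ions,
           monomer_mz = mono, ms2 = list(),
           provenance = list(study_id = "msp-import",
                             n_samples = NA_integer_, thresholds = NULL)),
      class = "ps_library_entry")
    lib <- add_entry(lib, entry)
    if (grepl("^UNKNOWN-", name)) {
      num <- suppressWarnings(as.integer(sub("^UNKNOWN-", "", name)))
      if (!is.na(num)) lib$next_unknown <- max(lib$next_unknown, num + 1L)
    }
  }
  lib
}

# Cosine similarity between two spectra on sqrt(relative area), pairing
# ions greedily by nearest mass within the mass window; unmatched ions
# contribute zero on the other side.
spectral_cosine <- function(mz_a, int_a, mz_b, int_b, mass_window) {
  a <- sqrt(int_a)
  b <- sqrt(int_b)
  d <- abs(outer(mz_a, mz_b, "-"))
  d[d > mass_window] <- NA
  pairs <- NULL
  while (any(is.finite(d))) {
    k <- arrayInd(which.min(d), dim(d))
    pairs <- rbind(pairs, k)
    d[k[1], ] <- NA
    d[, k[2]] <- NA
  }
  num <- if (is.null(pairs)) 0 else sum(a[pairs[, 1]] * b[pairs[, 2]])
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(0)
  num / den
}

entry_spectrum <- function(x, g = NULL, t = ps_thresholds()) {
  if (inherits(x, "ps_library_entry")) {
    list(mz = x$ions$mean_mz, int = x$ions$relative_area_pct,
         ri = x$ions$mean_ri[1])
  } else {
    stop("query must be a ps_library_entry (use build_library_entry())")
  }
}

#' Match a query spectrum against the library
#'
#' Library entries whose RI lies within `ri_match_window` of the query's
#' RI are scored by `100 *` the cosine similarity between the
#' square-root relative-area vectors, with ions paired within the mass
#' window. Results are sorted by score descending.
#'
#' @param query a `ps_library_entry` (build one from a group with
#'   [build_library_entry()]).
#' @param lib a `ps_library`.
#' @param t a [ps_thresholds()] object.
#' @return data.frame with `entry_id`, `name`, `score` (0-100),
#'   `matched_ions`, `ri_delta`; zero rows when the library is empty or
#'   nothing passes the RI gate.
#' @export
match_library <- function(query, lib, t = ps_thresholds()) {
  q <- entry_spectrum(query, t = t)
  rows <- lapply(lib$entries, function(e) {
    ri_delta <- e$ions$mean_ri[1] - q$ri
    if (!is.finite(ri_delta) || abs(ri_delta) > t$ri_match_window) {
      return(NULL)
    }
    d <- abs(outer(q$mz, e$ions$mean_mz, "-"))
    matched <- sum(apply(d <= t$mass_window, 1, any))
    score <- 100 * spectral_cosine(q$mz, q$int, e$ions$mean_mz,
                                   e$ions$relative_area_pct, t$mass_window)
    data.frame(entry_id = e$entry_id, name = e$name, score = score,
               matched_ions = matched, ri_delta = ri_delta)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(entry_id = character(0), name = character(0),
                      score = numeric(0), matched_ions = integer(0),
                      ri_delta = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Register an unmatched group as a new unknown
#'
#' When the best library match scores below `match_accept_score`, the
#' query becomes a new entry named `UNKNOWN-<n>` (ids strictly
#' increasing, never reused) with its chemical-intelligence annotations
#' attached, so the unknown entity can be tracked in future studies.
#'
#' @param query a `ps_library_entry`.
#' @param lib a `ps_library`.
#' @param t a [ps_thresholds()] object.
#' @return list with the updated `library`, the created `entry` (or
#'   `NULL` when the query matched), and the match `results`.
#' @export
register_unknown <- function(query, lib, t = ps_thresholds()) {
  res <- match_library(query, lib, t)
  if (nrow(res) > 0 && res$score[1] >= t$match_accept_score) {
    return(list(library = lib, entry = NULL, results = res))
  }
  query$name <- sprintf("UNKNOWN-%d", lib$next_unknown)
  lib$next_unknown <- lib$next_unknown + 1L
  lib <- add_entry(lib, query)
  list(library = lib, entry = lib$entries[[length(lib$entries)]],
       results = res)
}

#' @export
print.ps_library <- function(x, ...) {
  cat(sprintf("Spectral library: %d entries (next unknown id %d)\n",
              length(x$entries), x$next_unknown))
  invisible(x)
}

#' @export
print.ps_library_entry <- function(x, ...) {
  cat(sprintf("Library entry %s: %d ions, RI %.1f%s, %d MS2 spectra\n",
              x$name %||% "<unnamed>", nrow(x$ions), x$ions$mean_ri[1],
              if (is.finite(x$monomer_mz))
                sprintf(", monomer %.4f", x$monomer_mz) else "",
              length(x$ms2)))
  invisible(x)
}
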