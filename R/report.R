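# Per-residue modification maps, modification hot spots, and S/TPxK
# (cyclin-dependent-kinase target) motif annotation.

#' Build a per-residue modification map from localized sites
#'
#' Aggregates site-specific results into one row per modified position:
#' modification classes are deduplicated and per-class evidence (spectrum)
#' counts are summed. Re-aggregating an already aggregated map is a no-op.
#'
#' @param sites data.frame with columns `protein_id`, `position`, `residue`,
#'   `domain`, `mod_class` (or `class`) and optionally `n_spectra`
#'   (default 1 per row). [discover_ptms()] results restricted to
#'   site-specific rows qualify directly; rows that are not site-specific
#'   (when a `site_specific` column is present) raise an error.
#' @return An object of class `modification_map`: a data.frame with one row
#'   per (protein, position): `residue`, `domain`, `classes`
#'   (";"-joined, sorted), `n_classes`, `evidence` (";"-joined
#'   "class=count") and `n_spectra`; plus a long-format attribute used for
#'   re-aggregation.
#' @export
build_map <- function(sites) {
  if (inherits(sites, "modification_map")) sites <- attr(sites, "long")
  sites <- as.data.frame(sites)
  if (!is.null(sites$site_specific) && !all(sites$site_specific))
    stop("all input sites must be site-specific")
  if (is.null(sites$class) && !is.null(sites$mod_class))
    sites$class <- sites$mod_class
  need <- c("protein_id", "position", "residue", "class")
  if (!all(need %in% names(sites)))
    stop("missing columns: ", paste(setdiff(need, names(sites)), collapse = ", "))
  if (nrow(sites) == 0L) {
    out <- data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), domain = character(0),
                      classes = character(0), n_classes = integer(0),
                      evidence = character(0), n_spectra = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "long") <- sites[, intersect(names(sites), c(need, "domain",
                                                           "n_spectra"))]
    class(out) <- c("modification_map", class(out))
    return(out)
  }
  if (is.null(sites$n_spectra)) sites$n_spectra <- 1L
  if (is.null(sites$domain)) sites$domain <- NA_character_
  sites$domain <- ifelse(is.na(sites$domain), "", sites$domain)
  long <- stats::aggregate(n_spectra ~ protein_id + position + residue +
                             domain + class, data = sites, FUN = sum)
  key <- interaction(long$protein_id, long$position, drop = TRUE)
  rows <- lapply(split(long, key), function(g) {
    g <- g[order(g$class), , drop = FALSE]
    data.frame(protein_id = g$protein_id[1], position = g$position[1],
               residue = g$residue[1], domain = g$domain[1],
               classes = paste(unique(g$class), collapse = ";"),
               n_classes = length(unique(g$class)),
               evidence = paste(sprintf("%s=%d", g$class, g$n_spectra),
                                collapse = ";"),
               n_spectra = sum(g$n_spectra), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  out$domain[out$domain == ""] <- NA_character_
  rownames(out) <- NULL
  attr(out, "long") <- long
  class(out) <- c("modification_map", class(out))
  out
}

#' @export
print.modification_map <- function(x, ...) {
  cat(sprintf("<modification_map> %d modified position(s) on %d protein(s)\n",
              nrow(x), length(unique(x$protein_id))))
  if (nrow(x))
    print(as.data.frame(x)[, c("protein_id", "position", "residue", "domain",
                               "classes", "n_spectra")], row.names = FALSE)
  invisible(x)
}

#' Modification hot spots
#'
#' Positions carrying at least `k` distinct modification classes (single
#' residues were observed with up to four different modifications; the
#' default threshold is 3).
#'
#' @param map A [build_map()] result.
#' @param k Minimum number of distinct classes, >= 2.
#' @return data.frame (`protein_id`, `position`, `residue`,
#'   `distinct_mod_count`, `classes`) sorted by count (descending) then
#'   position.
#' @export
find_hot_spots <- function(map, k = 3L) {
  stopifnot(k >= 2)
  sel <- map$n_classes >= k
  out <- data.frame(protein_id = map$protein_id[sel],
                    position = map$position[sel],
                    residue = map$residue[sel],
                    distinct_mod_count = map$n_classes[sel],
                    classes = map$classes[sel], stringsAsFactors = FALSE)
  out <- out[order(-out$distinct_mod_count, out$protein_id, out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find S/TPxK motifs in a protein
#'
#' Scans for Ser/Thr - Pro - any - Lys, the cyclin-dependent-kinase target
#' motif of H1 tails. Overlapping matches are all reported. Positions are
#' Met-inclusive.
#'
#' @param protein A [protein_record()] (or plain sequence, taken as offset 1).
#' @return data.frame (`position` of the S/T, `motif`).
#' @export
find_stpxk_motifs <- function(protein) {
  if (is.character(protein)) protein <- protein_record("seq", protein)
  seq <- protein$sequence
  m <- gregexpr("(?=[ST]P.K)", seq, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(position = integer(0), motif = character(0),
                      stringsAsFactors = FALSE))
  starts <- as.integer(m)
  data.frame(position = mature_to_coord(protein, starts),
             motif = substring(seq, starts, starts + 3L),
             stringsAsFactors = FALSE)
}

#' Flag map rows that fall inside S/TPxK motifs
#'
#' Adds a logical `in_stpxk` column: lysine (or phosphoacceptor)
#' modifications inside a CDK target motif can interfere with kinase
#' recognition; only the boolean flag is computed, no functional claim.
#'
#' @param map A [build_map()] result.
#' @param proteins List of [protein_record()] objects covering the map.
#' @return The map with an `in_stpxk` column.
#' @export
annotate_cdk_motifs <- function(map, proteins) {
  ids <- vapply(proteins, `[[`, character(1), "id")
  map$in_stpxk <- FALSE
  for (p in proteins) {
    motifs <- find_stpxk_motifs(p)
    if (!nrow(motifs)) next
    sel <- map$protein_id == p$id
    for (s in motifs$position)
      map$in_stpxk <- map$in_stpxk |
        (sel & map$position >= s & map$position <= s + 3L)
  }
  map
}

#' Write a modification map as TSV, JSON, or a plain-text track
#'
#' @param map A [build_map()] result.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @export
write_map <- function(map, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(map)
  attr(df, "long") <- NULL
  if (format == "tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  else
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Plain-text per-residue modification track
#'
#' Renders the protein sequence with a marker line: `*` under residues with
#' one modification class, digits for multi-class positions.
#'
#' @param map A [build_map()] result (rows for `protein`).
#' @param protein A [protein_record()].
#' @param width Residues per line.
#' @return Character vector of lines (invisibly printed with `cat`).
#' @export
render_track <- function(map, protein, width = 60L) {
  seq <- protein$sequence
  n <- nchar(seq)
  marks <- rep(" ", n)
  rows <- map[map$protein_id == protein$id, , drop = FALSE]
  for (r in seq_len(nrow(rows))) {
    i <- coord_to_mature(protein, rows$position[r])
    if (i >= 1 && i <= n)
      marks[i] <- if (rows$n_classes[r] > 1) as.character(rows$n_classes[r])
                  else "*"
  }
  lines <- character(0)
  for (s in seq(1, n, by = width)) {
    e <- min(n, s + width - 1L)
    lines <- c(lines,
               sprintf("%6d %s", mature_to_coord(protein, s),
                       substr(seq, s, e)),
               sprintf("       %s", paste(marks[s:e], collapse = "")))
  }
  lines
}
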