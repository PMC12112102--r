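# PT -> System Organ Class lookup. MedDRA itself is licensed and never
# bundled; users supply their own two-column mapping. The package ships only
# a small synthetic fixture (inst/extdata/synthetic_pt_soc.tsv) for examples.

#' Load a preferred-term to System Organ Class mapping
#'
#' Reads a two-column delimited file (`pt`, `soc`). Preferred terms are
#' normalized (upper-case, trimmed) so lookups are case-insensitive;
#' duplicate rows that agree on the SOC collapse, duplicates that disagree
#' are an error, since each PT belongs to exactly one primary SOC.
#'
#' @param path Two-column TSV/CSV with header columns `pt` and `soc`.
#' @param version_label Free-text label recorded with the mapping (e.g. the
#'   dictionary version the user exported it from).
#' @return A `pt_soc_map`: named character vector (names = normalized PTs,
#'   values = SOC labels) with a `version_label` attribute.
#' @export
load_pt_soc <- function(path, version_label = "unversioned") {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (!all(c("pt", "soc") %in% names(tab))) {
    stop("mapping file must have columns 'pt' and 'soc'", call. = FALSE)
  }
  if (nrow(tab) == 0) stop("empty mapping file: ", path, call. = FALSE)
  tab$pt <- normalize_term(tab$pt)
  tab$soc <- trimws(tab$soc)
  tab <- unique(tab[c("pt", "soc")])
  dup <- tab$pt[duplicated(tab$pt)]
  if (length(dup) > 0) {
    stop("conflicting SOC assignments for PT(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(tab$soc, tab$pt),
            version_label = version_label, class = "pt_soc_map")
}

#' @export
print.pt_soc_map <- function(x, ...) {
  cat("<pt_soc_map> ", length(x), " preferred terms, ",
      length(unique(unname(unclass(x)))), " SOCs (",
      attr(x, "version_label"), ")\n", sep = "")
  invisible(x)
}

#' Look up the SOC of preferred terms
#'
#' @param pts Character vector of preferred terms (any case).
#' @param mapping A `pt_soc_map` from [load_pt_soc()], or `NULL`.
#' @return Character vector of SOC labels; unmapped terms (or a `NULL`
#'   mapping) give `"UNMAPPED"`.
#' @export
soc_of <- function(pts, mapping) {
  if (is.null(mapping)) return(rep("UNMAPPED", length(pts)))
  stopifnot(inherits(mapping, "pt_soc_map"))
  hit <- unname(unclass(mapping)[normalize_term(pts)])
  ifelse(is.na(hit), "UNMAPPED", hit)
}

#' Aggregate PT occurrence counts by System Organ Class
#'
#' Sums per-PT occurrence counts within each SOC (one occurrence = one
#' (report, PT) pair, within-report duplicates already collapsed) and
#' reports each SOC's share of the occurrence total. Terms absent from the
#' mapping are routed to the reserved class `UNMAPPED`, so the SOC counts
#' always partition the occurrence total.
#'
#' @param occurrences Tibble/data.frame with columns `pt` and `n` (per-PT
#'   occurrence counts), e.g. from [pt_occurrences()].
#' @param mapping A `pt_soc_map`, or `NULL` to route everything to
#'   `UNMAPPED`.
#' @return Tibble with columns `soc`, `n`, `percent` (share of total
#'   occurrences, one decimal, half-up), sorted by `n` descending then SOC.
#' @export
soc_aggregate <- function(occurrences, mapping = NULL) {
  stopifnot(all(c("pt", "n") %in% names(occurrences)))
  if (nrow(occurrences) == 0) {
    return(tibble::tibble(soc = character(0), n = integer(0), percent = numeric(0)))
  }
  total <- sum(occurrences$n)
  occurrences |>
    dplyr::mutate(soc = soc_of(.data$pt, mapping)) |>
    dplyr::group_by(.data$soc) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(percent = percent_of(.data$n, total)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$soc)
}
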