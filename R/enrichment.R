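#' Read a GMT pathway annotation file
#'
#' Standard GMT: one pathway per line, tab-separated — name, description
#' (used here as the top-level category name), then member symbols. Member
#' symbols are uppercased so matching downstream is case-insensitive.
#'
#' @param path GMT file.
#' @return tibble: `pathway`, `top_name`, `members` (list column of
#'   uppercased symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3)
  if (length(short)) {
    stop("GMT parse error: fewer than 3 fields at line ", short[1])
  }
  ann <- tibble::tibble(
    pathway = vapply(fields, `[[`, "", 1),
    top_name = vapply(fields, `[[`, "", 2),
    members = lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  )
  dup <- duplicated(ann$pathway)
  if (any(dup)) {
    stop("duplicate pathway name(s): ",
         paste(unique(ann$pathway[dup]), collapse = ", "))
  }
  if (any(vapply(ann$members, length, 0L) == 0)) {
    stop("pathway with empty member set")
  }
  ann
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway: `m` = pathway members present in the background, `q` =
#' members present in the query, `ratio = q / m`, and the upper-tail
#' hypergeometric probability `p = P(X >= q)` of drawing at least `q`
#' pathway members when `|query|` proteins are drawn without replacement
#' from the background. Only pathways with `m >= min_m` background members
#' are reported, sorted by ratio (descending) then p (ascending). P-values
#' are reported raw — no multiple-testing correction.
#'
#' @param query protein symbols of interest (must lie in `background`;
#'   strays are dropped with a warning).
#' @param background the reference proteome (here: all panel proteins that
#'   survived QC).
#' @param pathways annotation tibble from [read_gmt()] / [simulate_gmt()].
#' @param min_m minimum background members per reported pathway.
#' @return tibble: pathway, top_name, q, m, p, ratio, proteins
#'   (pipe-separated hit symbols).
#' @export
enrich <- function(query, background, pathways, min_m = 5) {
  background <- unique(toupper(background))
  if (!length(background)) stop("empty background")
  query <- unique(toupper(query))
  stray <- setdiff(query, background)
  if (length(stray)) {
    warning("query protein(s) not in background, dropped: ",
            paste(head(stray, 5), collapse = ", "))
    query <- intersect(query, background)
  }
  N <- length(background)
  n_draw <- length(query)
  rows <- purrr::pmap_dfr(pathways, function(pathway, top_name, members, ...) {
    bg_hit <- intersect(members, background)
    m <- length(bg_hit)
    if (m < min_m) return(NULL)
    hits <- intersect(members, query)
    q <- length(hits)
    tibble::tibble(
      pathway = pathway, top_name = top_name,
      q = q, m = m,
      p = phyper(q - 1, m, N - m, n_draw, lower.tail = FALSE),
      ratio = q / m,
      proteins = paste(sort(hits), collapse = "|")
    )
  })
  if (!nrow(rows)) {
    return(tibble::tibble(pathway = character(), top_name = character(),
                          q = integer(), m = integer(), p = numeric(),
                          ratio = numeric(), proteins = character()))
  }
  dplyr::arrange(rows, dplyr::desc(.data$ratio), .data$p, .data$pathway)
}

#' The three enrichment analyses of the pipeline
#'
#' Runs over-representation analysis for (A) the differentially abundant
#' proteins, (B) the proteins dominating co-expression in the control
#' group, and (C) those dominating in the case group, against one shared
#' background (all analyzed panel proteins).
#'
#' @param de_proteins,coex_control_set,coex_case_set query protein vectors.
#' @param background shared background proteome.
#' @param pathways annotation tibble.
#' @param min_m minimum background members per reported pathway.
#' @return named list of three enrichment tibbles: `A_differential`,
#'   `B_coexpression_control`, `C_coexpression_case`.
#' @export
run_three_analyses <- function(de_proteins, coex_control_set, coex_case_set,
                               background, pathways, min_m = 5) {
  list(
    A_differential = enrich(de_proteins, background, pathways, min_m),
    B_coexpression_control = enrich(coex_control_set, background, pathways,
                                    min_m),
    C_coexpression_case = enrich(coex_case_set, background, pathways, min_m)
  )
}
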