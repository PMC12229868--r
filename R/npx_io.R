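npx_required_cols <- c("sample_id", "person_id", "assay_id", "panel",
                       "dilution", "npx", "lod", "uloq", "qc_pass")

#' Read a long-format NPX table
#'
#' Reads the CSV dialect used throughout the package: one row per sample x
#' assay x dilution with columns `sample_id, person_id, assay_id, panel,
#' dilution, npx, lod, uloq, qc_pass`. NPX, LOD and ULOQ are log2-scale;
#' `lod < uloq` bound the assay's dynamic range.
#'
#' @param path CSV file path.
#' @return validated tibble of NPX records.
#' @export
read_npx_long <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_npx_long(tbl)
}

#' Validate an in-memory NPX table
#'
#' Checks required columns, positive dilutions, `lod < uloq`, and uniqueness
#' of the (sample, assay, dilution) key.
#'
#' @param tbl data frame of NPX records.
#' @return the table as a tibble, invisibly validated.
#' @export
validate_npx_long <- function(tbl) {
  missing_cols <- setdiff(npx_required_cols, names(tbl))
  if (length(missing_cols)) {
    stop("NPX table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tbl <- tibble::as_tibble(tbl)
  bad <- which(tbl$lod >= tbl$uloq)
  if (length(bad)) {
    stop("lod >= uloq in row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  if (any(tbl$dilution <= 0)) {
    stop("non-positive dilution in row(s): ",
         paste(head(which(tbl$dilution <= 0), 5), collapse = ", "))
  }
  key <- paste(tbl$sample_id, tbl$assay_id, tbl$dilution, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    k <- strsplit(key[which(dup)[1]], "\r")[[1]]
    stop("duplicate (sample, assay, dilution) key: (",
         paste(k, collapse = ", "), ")")
  }
  tbl
}

#' Read a sample metadata table
#'
#' @param path CSV with columns person_id, group, age, sex, bmi.
#' @return tibble with `group` checked against \{control, OA\} and both
#'   groups non-empty.
#' @export
read_samples <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("person_id", "group", "age", "sex", "bmi")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    stop("sample table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tbl$person_id)) stop("duplicated person_id in sample table")
  if (!all(tbl$group %in% c("control", "OA"))) {
    stop("group must be 'control' or 'OA'")
  }
  if (length(unique(tbl$group)) < 2) stop("both groups must be non-empty")
  tibble::as_tibble(tbl)
}

# per-assay, per-dilution median distance to the middle of the dynamic range
dilution_distances <- function(tbl) {
  tbl |>
    dplyr::mutate(mid = (.data$lod + .data$uloq) / 2) |>
    dplyr::group_by(.data$assay_id, .data$dilution) |>
    dplyr::summarise(
      median_dist = median(abs(.data$npx - .data$mid)),
      any_in_range = any(.data$npx > .data$lod & .data$npx < .data$uloq),
      .groups = "drop"
    )
}

#' Select the dilution closest to the middle of the dynamic range
#'
#' For each assay measured at several dilutions, picks the dilution whose
#' NPX values sit closest to the centre `(lod + uloq) / 2` of the dynamic
#' range, operationalized as the minimum over dilutions of the median
#' per-sample distance to the centre. Ties break toward the smaller
#' dilution factor. Assays with no in-range value at any dilution are
#' flagged (`no_in_range`), not dropped.
#'
#' @param tbl long NPX table.
#' @param assay_id optional single assay; when given, returns that assay's
#'   chosen dilution as a scalar.
#' @return tibble with columns `assay_id`, `dilution`, `median_dist`,
#'   `no_in_range` (or a scalar dilution when `assay_id` is given).
#' @export
select_dilution <- function(tbl, assay_id = NULL) {
  if (!is.null(assay_id)) {
    tbl <- tbl[tbl$assay_id %in% assay_id, , drop = FALSE]
    if (!nrow(tbl)) stop("assay not present: ", assay_id)
  }
  dist <- dilution_distances(tbl)
  chosen <- dist |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::arrange(.data$median_dist, .data$dilution, .by_group = TRUE) |>
    dplyr::summarise(
      dilution = dplyr::first(.data$dilution),
      median_dist = dplyr::first(.data$median_dist),
      no_in_range = !any(.data$any_in_range),
      .groups = "drop"
    )
  if (!is.null(assay_id)) return(chosen$dilution[[1]])
  chosen
}

#' Dilution-linearity deviation score
#'
#' For each sample and each adjacent pair of dilutions `d1 < d2`, the
#' observed shift is `npx(d1) - npx(d2)` and the predicted shift is
#' `log2(d2 / d1)`. The score is the mean absolute deviation between the
#' two, in log2 units; 0 means perfect dilution behaviour. Assays measured
#' at a single dilution return `NA` (not applicable, assay retained).
#'
#' @param tbl long NPX table.
#' @param assay_id assay to score (scalar) or `NULL` for all assays.
#' @return scalar score, or tibble `assay_id`, `linearity_score`.
#' @export
dilution_linearity_score <- function(tbl, assay_id = NULL) {
  one <- function(sub) {
    factors <- sort(unique(sub$dilution))
    if (length(factors) < 2) return(NA_real_)
    wide <- sub |>
      dplyr::select("sample_id", "dilution", "npx") |>
      tidyr::pivot_wider(names_from = "dilution", values_from = "npx")
    devs <- vapply(seq_len(length(factors) - 1), function(i) {
      d1 <- factors[i]; d2 <- factors[i + 1]
      obs <- wide[[as.character(d1)]] - wide[[as.character(d2)]]
      mean(abs(obs - log2(d2 / d1)), na.rm = TRUE)
    }, 0)
    mean(devs)
  }
  if (!is.null(assay_id)) {
    sub <- tbl[tbl$assay_id %in% assay_id, , drop = FALSE]
    if (!nrow(sub)) stop("assay not present: ", assay_id)
    return(one(sub))
  }
  tbl |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::group_modify(~ tibble::tibble(linearity_score = one(.x))) |>
    dplyr::ungroup()
}

#' Exclude assays with too many below-LOD values in a group
#'
#' An assay is excluded when more than `max_below` samples *within either
#' group* fall below the assay's LOD. In retained assays, individual
#' below-LOD cells are set to missing (they are considered unreliable, not
#' imputed).
#'
#' @param tbl long NPX table with one row per sample x assay (dilution
#'   already selected).
#' @param samples sample metadata table (person_id, group, ...).
#' @param max_below maximum tolerated below-LOD count per group (default 2,
#'   i.e. "more than two" excludes).
#' @return list with `data` (retained table, below-LOD cells `NA`),
#'   `excluded` (tibble assay_id, reason) and `below_lod_counts` (tibble
#'   assay_id, group, n_below).
#' @export
filter_lod <- function(tbl, samples, max_below = 2) {
  joined <- dplyr::left_join(tbl, samples[, c("person_id", "group")],
                             by = "person_id")
  counts <- joined |>
    dplyr::group_by(.data$assay_id, .data$group) |>
    dplyr::summarise(n_below = sum(.data$npx < .data$lod, na.rm = TRUE),
                     .groups = "drop")
  excluded_ids <- counts |>
    dplyr::filter(.data$n_below > max_below) |>
    dplyr::distinct(.data$assay_id) |>
    dplyr::pull()
  retained <- tbl |>
    dplyr::filter(!(.data$assay_id %in% excluded_ids)) |>
    dplyr::mutate(npx = ifelse(.data$npx < .data$lod, NA_real_, .data$npx))
  list(
    data = retained,
    excluded = tibble::tibble(assay_id = excluded_ids,
                              reason = rep("below_lod", length(excluded_ids))),
    below_lod_counts = counts
  )
}

#' Run the full NPX quality-control stage
#'
#' Applies, in order: dilution selection within the dynamic range,
#' dilution-linearity exclusion, and below-LOD exclusion/masking. Returns
#' the analysis-ready table (one row per sample x assay) plus a QC report
#' in which every input assay appears exactly once (retained or excluded
#' with a reason).
#'
#' @param tbl long NPX table (possibly multi-dilution).
#' @param samples sample metadata table.
#' @param linearity_threshold maximum tolerated linearity score (log2
#'   units); assays scoring above it are excluded with reason
#'   `nonlinearity`.
#' @param max_below below-LOD tolerance per group, see [filter_lod()].
#' @return list with `data` (retained long table at the chosen dilution,
#'   below-LOD cells `NA`) and `report` (an `npx_qc` object).
#' @export
qc_npx <- function(tbl, samples, linearity_threshold = 1, max_below = 2) {
  tbl <- validate_npx_long(tbl)
  all_assays <- sort(unique(tbl$assay_id))

  lin <- dilution_linearity_score(tbl)
  nonlinear <- lin$assay_id[!is.na(lin$linearity_score) &
                              lin$linearity_score > linearity_threshold]

  chosen <- select_dilution(tbl)
  selected <- tbl |>
    dplyr::inner_join(chosen[, c("assay_id", "dilution")],
                      by = c("assay_id", "dilution")) |>
    dplyr::filter(!(.data$assay_id %in% nonlinear))

  lodres <- filter_lod(selected, samples, max_below = max_below)

  excluded <- dplyr::bind_rows(
    tibble::tibble(assay_id = nonlinear,
                   reason = rep("nonlinearity", length(nonlinear))),
    lodres$excluded
  )
  retained_assays <- sort(unique(lodres$data$assay_id))
  stopifnot(setequal(c(retained_assays, excluded$assay_id), all_assays),
            !anyDuplicated(c(retained_assays, excluded$assay_id)))

  report <- structure(list(
    chosen_dilutions = chosen,
    linearity = lin,
    excluded = excluded,
    retained = retained_assays,
    below_lod_counts = lodres$below_lod_counts,
    linearity_threshold = linearity_threshold,
    max_below = max_below,
    n_assays_in = length(all_assays)
  ), class = "npx_qc")
  list(data = lodres$data, report = report)
}

#' @export
print.npx_qc <- function(x, ...) {
  cat("NPX quality-control report\n")
  cat("  assays in:      ", x$n_assays_in, "\n")
  cat("  assays retained:", length(x$retained), "\n")
  if (nrow(x$excluded)) {
    for (i in seq_len(nrow(x$excluded))) {
      cat("  excluded:", x$excluded$assay_id[i],
          paste0("(", x$excluded$reason[i], ")"), "\n")
    }
  } else {
    cat("  no exclusions\n")
  }
  invisible(x)
}

qc_report_json <- function(report, path) {
  jsonlite::write_json(list(
    n_assays_in = report$n_assays_in,
    retained = report$retained,
    excluded = report$excluded,
    chosen_dilutions = report$chosen_dilutions,
    below_lod_counts = report$below_lod_counts,
    linearity = report$linearity,
    thresholds = list(linearity = report$linearity_threshold,
                      max_below_lod = report$max_below)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
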