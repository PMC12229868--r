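#' Build a planted precision matrix
#'
#' Constructs a sparse symmetric positive-definite precision matrix over `p`
#' variables with the given off-diagonal edges, for planting
#' conditional-dependence structure in simulated data. A nonzero entry of the
#' precision matrix corresponds to an edge of the Gaussian graphical model.
#'
#' @param p number of variables.
#' @param edges two-column integer matrix of edge endpoints (1-based).
#' @param weight off-diagonal precision value placed on each edge.
#' @return a `p x p` positive-definite matrix.
#' @export
planted_precision <- function(p, edges, weight = 0.3) {
  P <- diag(p)
  if (length(edges)) {
    edges <- matrix(as.integer(edges), ncol = 2)
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      P[i, j] <- P[j, i] <- weight
    }
  }
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    # diagonal boost keeps the requested pattern while restoring PD
    P <- P + diag(p) * (abs(min(ev)) + 0.05)
  }
  P
}

default_network_structure <- function(ids) {
  p <- length(ids)
  stopifnot(p >= 4)
  chain <- cbind(seq_len(p - 1), seq_len(p - 1) + 1)
  shared <- chain[chain[, 1] > floor(p / 2), , drop = FALSE]
  control_only <- chain[chain[, 1] <= floor(p / 2), , drop = FALSE]
  skip <- cbind(seq_len(p - 2), seq_len(p - 2) + 2)
  case_only <- skip[skip[, 1] <= floor(p / 2) - 1, , drop = FALSE]
  list(
    control_edges = rbind(shared, control_only),
    case_edges = rbind(shared, case_only),
    control_only = control_only,
    case_only = case_only
  )
}

#' Simulation configuration for synthetic NPX datasets
#'
#' Defaults emulate a two-group synovial-fluid panel study: 13 control
#' persons and 11 cases measured on three 92-assay panels (two of them run at
#' several dilutions), log2-scale values with per-person random intercepts,
#' age/sex/BMI covariate effects, group mean shifts for a subset of proteins
#' (105 up-shifted to +3.4 log2 units, 35 down-shifted to -5.06, matching
#' fold changes between 0.03 and 10.6), group-specific conditional-dependence
#' structure over a 30-protein subset, LOD/ULOQ censoring thresholds set as
#' marginal quantiles, two assays with corrupted (saturating) dilution
#' behaviour and one chronically low-abundance assay.
#'
#' @param n_control,n_case persons per group (>= 3).
#' @param panels named integer vector: assays per panel.
#' @param dilution_factors named list of strictly increasing positive
#'   dilution ratios per panel.
#' @param log2_effects named per-protein group shift (log2 units); `NULL`
#'   draws the default pattern described above from the seed.
#' @param covariate_effects named coefficients `age` (per year), `sex`
#'   (M vs F) and `bmi` (per kg/m^2) on the log2 scale.
#' @param person_sd random person-intercept standard deviation (log2 units).
#' @param residual_sd residual standard deviation for proteins outside the
#'   correlated subset (log2 units).
#' @param network_proteins assay ids carrying correlated noise; `NULL` uses
#'   the first 30 assays.
#' @param control_precision,case_precision symmetric positive-definite
#'   precision matrices over `network_proteins`; `NULL` builds a default
#'   pair sharing some edges and differing in others.
#' @param lod_quantile,uloq_quantile censoring thresholds as quantiles of
#'   each assay's marginal value distribution.
#' @param dilution_noise_sd measurement noise added per dilution (log2).
#' @param bad_assay_ids assays given a corrupted (hook/saturation) dilution
#'   series; `NULL` picks two multi-dilution assays.
#' @param low_assay_ids assays forced below LOD for several control samples
#'   (emulating a vWF-like exclusion); `NULL` picks one.
#' @param seed integer master seed; every stage draws from a named substream.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_control = 13, n_case = 11,
                              panels = c(CAM = 92, CVD3 = 92, DEV = 92),
                              dilution_factors = list(CAM = c(1, 200, 1000),
                                                      CVD3 = c(1, 20, 200),
                                                      DEV = 1),
                              log2_effects = NULL,
                              covariate_effects = c(age = 0.01, sex = 0.25, bmi = 0.02),
                              person_sd = 0.5, residual_sd = 1,
                              network_proteins = NULL,
                              control_precision = NULL, case_precision = NULL,
                              lod_quantile = 0.02, uloq_quantile = 0.995,
                              dilution_noise_sd = 0.05,
                              bad_assay_ids = NULL, low_assay_ids = NULL,
                              seed = 1) {
  n_proteins <- sum(panels)
  assay_ids <- sprintf("P%03d", seq_len(n_proteins))
  panel_of <- rep(names(panels), panels)
  names(panel_of) <- assay_ids

  if (is.null(log2_effects)) {
    log2_effects <- setNames(numeric(n_proteins), assay_ids)
    n_up <- min(105L, n_proteins)
    n_down <- min(35L, max(n_proteins - n_up, 0L))
    if (n_up + n_down > 0 && n_proteins >= n_up + n_down) {
      log2_effects[] <- with_substream(seed, "effects", {
        hit <- sample(n_proteins, n_up + n_down)
        e <- numeric(n_proteins)
        e[hit[seq_len(n_up)]] <- runif(n_up, 0.3, 3.4)
        if (n_down > 0) e[hit[n_up + seq_len(n_down)]] <- -runif(n_down, 0.3, 5.06)
        e
      })
    }
  }
  if (is.null(names(log2_effects))) names(log2_effects) <- assay_ids[seq_along(log2_effects)]

  if (is.null(network_proteins)) {
    network_proteins <- if (n_proteins >= 8) {
      assay_ids[seq_len(min(30L, n_proteins))]
    } else {
      character(0)
    }
  }
  if (length(network_proteins)) {
    if (is.null(control_precision) || is.null(case_precision)) {
      structure_default <- default_network_structure(network_proteins)
      if (is.null(control_precision)) {
        control_precision <- planted_precision(length(network_proteins),
                                               structure_default$control_edges)
      }
      if (is.null(case_precision)) {
        case_precision <- planted_precision(length(network_proteins),
                                            structure_default$case_edges)
      }
    }
    dimnames(control_precision) <- list(network_proteins, network_proteins)
    dimnames(case_precision) <- list(network_proteins, network_proteins)
  } else {
    control_precision <- case_precision <- matrix(0, 0, 0)
  }

  multi <- assay_ids[panel_of %in% names(dilution_factors)[
    vapply(dilution_factors, length, 1L) > 1]]
  if (is.null(bad_assay_ids)) {
    bad_assay_ids <- setdiff(multi, network_proteins)[1:2]
    bad_assay_ids <- bad_assay_ids[!is.na(bad_assay_ids)]
  }
  if (is.null(low_assay_ids)) {
    low_assay_ids <- setdiff(assay_ids, c(network_proteins, bad_assay_ids))
    low_assay_ids <- low_assay_ids[length(low_assay_ids)]
  }

  cfg <- structure(list(
    n_control = n_control, n_case = n_case, n_proteins = n_proteins,
    panels = panels, assay_ids = assay_ids, panel_of = panel_of,
    dilution_factors = dilution_factors,
    log2_effects = log2_effects, covariate_effects = covariate_effects,
    person_sd = person_sd, residual_sd = residual_sd,
    network_proteins = network_proteins,
    control_precision = control_precision, case_precision = case_precision,
    lod_quantile = lod_quantile, uloq_quantile = uloq_quantile,
    dilution_noise_sd = dilution_noise_sd,
    bad_assay_ids = bad_assay_ids, low_assay_ids = low_assay_ids,
    seed = as.integer(seed)
  ), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_control < 3 || cfg$n_case < 3) {
    stop("n_control and n_case must both be >= 3")
  }
  if (!all(is.finite(cfg$log2_effects))) stop("log2_effects must be finite")
  for (nm in names(cfg$dilution_factors)) {
    f <- cfg$dilution_factors[[nm]]
    if (!length(f)) stop("empty dilution factor list for panel ", nm)
    if (any(f <= 0) || is.unsorted(f, strictly = TRUE)) {
      stop("dilution_factors for panel ", nm,
           " must be strictly increasing and positive")
    }
  }
  for (nm in c("control_precision", "case_precision")) {
    P <- cfg[[nm]]
    if (!nrow(P)) next
    if (!isSymmetric(unname(P), tol = 1e-8)) {
      stop(nm, " is not symmetric")
    }
    ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop(nm, " is not positive definite (smallest eigenvalue ",
           format(min(ev)), ")")
    }
  }
  invisible(cfg)
}

#' Simulate an NPX dilution series
#'
#' A well-behaved assay diluted by factor `d` relative to the reference
#' (smallest) factor shifts its log2 NPX value by `-log2(d / d_ref)`, plus
#' measurement noise. A corrupted assay emulates a saturation/hook artifact:
#' ideal values above a cap (set just below the most-dilute level) fold back
#' beneath it, so the observed inter-dilution shift departs strongly from
#' the predicted log2 ratio and the assay fails dilution-linearity QC.
#'
#' @param base_values per-sample log2 values at the reference dilution.
#' @param factors strictly increasing positive dilution ratios.
#' @param corrupt apply the saturating transform?
#' @param noise_sd per-cell measurement noise SD (log2 units); 0 for exact.
#' @return matrix, samples x dilutions, colnames the factors.
#' @export
simulate_dilution_series <- function(base_values, factors, corrupt = FALSE,
                                     noise_sd = 0) {
  if (!length(factors)) stop("empty dilution factor list")
  if (any(factors <= 0)) stop("dilution factors must be positive")
  if (is.unsorted(factors, strictly = TRUE)) {
    stop("dilution factors must be strictly increasing")
  }
  ref <- factors[1]
  ideal <- outer(base_values, factors, function(v, d) v - log2(d / ref))
  if (corrupt) {
    cap <- min(ideal[, length(factors)]) - 0.1
    ideal <- ifelse(ideal > cap, cap - (ideal - cap), ideal)
  }
  out <- ideal
  if (noise_sd > 0) {
    out <- out + matrix(rnorm(length(ideal), sd = noise_sd), nrow = nrow(ideal))
  }
  colnames(out) <- as.character(factors)
  rownames(out) <- names(base_values)
  out
}

#' Simulate a synthetic NPX panel dataset with known ground truth
#'
#' Generates a long-format NPX table (one row per sample x assay x
#' dilution), a sample metadata table and a truth record. Values are built
#' on the log2 scale as: protein baseline + group shift (cases only) +
#' age/sex/BMI covariate terms + person random intercept + noise. Proteins
#' in `config$network_proteins` receive correlated noise drawn from the
#' group's precision matrix (so control and case samples carry different
#' conditional-dependence structure); all other proteins get independent
#' noise. Per-assay LOD/ULOQ are set as marginal quantiles after dilution
#' simulation; a designated low-abundance assay is pushed below LOD for
#' several control samples, and designated bad assays get corrupted dilution
#' series. All draws are deterministic functions of `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `npx` (long tibble: sample_id, person_id,
#'   assay_id, panel, dilution, npx, lod, uloq, qc_pass), `samples` (tibble:
#'   person_id, group, age, sex, bmi) and `truth` (list: log2_effects,
#'   differential_edges, censored_cells, corrupted_assays, low_assays,
#'   network_proteins).
#' @export
simulate_npx_dataset <- function(config = simulation_config()) {
  validate_simulation_config(config)
  seed <- config$seed
  n_c <- config$n_control; n_o <- config$n_case
  persons <- c(sprintf("C%02d", seq_len(n_c)), sprintf("O%02d", seq_len(n_o)))
  group <- rep(c("control", "OA"), c(n_c, n_o))
  n_persons <- n_c + n_o

  samples <- with_substream(seed, "covariates", tibble::tibble(
    person_id = persons,
    group = group,
    age = round(runif(n_persons, 18, 79), 1),
    sex = ifelse(rbinom(n_persons, 1, 0.5) == 1, "M", "F"),
    bmi = round(rnorm(n_persons, 27, 4), 1)
  ))

  assay_ids <- config$assay_ids
  p <- length(assay_ids)
  baselines <- with_substream(seed, "baselines",
                              setNames(runif(p, 2, 10), assay_ids))
  effects <- setNames(numeric(p), assay_ids)
  effects[names(config$log2_effects)] <- config$log2_effects

  ce <- config$covariate_effects
  cov_term <- ce[["age"]] * (samples$age - mean(samples$age)) +
    ce[["sex"]] * (samples$sex == "M") +
    ce[["bmi"]] * (samples$bmi - mean(samples$bmi))
  person_int <- with_substream(seed, "person",
                               rnorm(n_persons, sd = config$person_sd))

  net <- config$network_proteins
  others <- setdiff(assay_ids, net)
  noise <- matrix(0, n_persons, p, dimnames = list(persons, assay_ids))
  noise[] <- with_substream(seed, "noise", {
    nz <- matrix(0, n_persons, p)
    colnames(nz) <- assay_ids
    if (length(net)) {
      sigma_c <- solve(config$control_precision)
      sigma_o <- solve(config$case_precision)
      nz[group == "control", net] <-
        MASS::mvrnorm(n_c, mu = rep(0, length(net)), Sigma = sigma_c)
      nz[group == "OA", net] <-
        MASS::mvrnorm(n_o, mu = rep(0, length(net)), Sigma = sigma_o)
    }
    if (length(others)) {
      nz[, others] <- rnorm(n_persons * length(others), sd = config$residual_sd)
    }
    nz
  })

  base <- outer(rep(1, n_persons), baselines) +
    outer(as.numeric(group == "OA"), effects) +
    matrix(cov_term + person_int, n_persons, p) + noise
  dimnames(base) <- list(persons, assay_ids)

  long <- with_substream(seed, "dilution", {
    pieces <- lapply(assay_ids, function(a) {
      pan <- config$panel_of[[a]]
      factors <- config$dilution_factors[[pan]]
      vals <- simulate_dilution_series(base[, a], factors,
                                       corrupt = a %in% config$bad_assay_ids,
                                       noise_sd = config$dilution_noise_sd)
      tibble::tibble(
        sample_id = rep(persons, times = length(factors)),
        person_id = rep(persons, times = length(factors)),
        assay_id = a,
        panel = pan,
        dilution = rep(factors, each = n_persons),
        npx = as.vector(vals)
      )
    })
    dplyr::bind_rows(pieces)
  })

  limits <- long |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(
      lod = quantile(.data$npx, config$lod_quantile, names = FALSE),
      uloq = quantile(.data$npx, config$uloq_quantile, names = FALSE) + 1e-9,
      .groups = "drop"
    )
  long <- dplyr::left_join(long, limits, by = "assay_id")

  # low-abundance assay: push the first 4 control samples below LOD at every
  # dilution, mimicking an assay excluded for >2 below-LOD values in a group
  low_cells <- NULL
  if (length(config$low_assay_ids)) {
    low_samples <- persons[group == "control"][1:4]
    idx <- long$assay_id %in% config$low_assay_ids &
      long$sample_id %in% low_samples
    long$npx[idx] <- long$lod[idx] - 1
  }
  long$qc_pass <- TRUE
  censored <- long |>
    dplyr::filter(.data$npx < .data$lod) |>
    dplyr::select("sample_id", "assay_id", "dilution")

  diff_edges <- differential_truth_edges(config)

  truth <- list(
    log2_effects = effects,
    differential_edges = diff_edges,
    censored_cells = censored,
    corrupted_assays = config$bad_assay_ids,
    low_assays = config$low_assay_ids,
    network_proteins = net
  )
  stopifnot(all(c(diff_edges$protein_a, diff_edges$protein_b) %in% assay_ids))
  list(npx = long, samples = samples, truth = truth)
}

# pairs whose precision entries differ in support between the groups
differential_truth_edges <- function(config) {
  net <- config$network_proteins
  Pc <- abs(config$control_precision) > 1e-10
  Po <- abs(config$case_precision) > 1e-10
  diag(Pc) <- diag(Po) <- FALSE
  idx <- which((Pc != Po) & upper.tri(Pc), arr.ind = TRUE)
  tibble::tibble(
    protein_a = net[idx[, 1]],
    protein_b = net[idx[, 2]],
    present_in = ifelse(Pc[idx], "control", "OA")
  )
}

#' Simulate a GMT-style pathway annotation
#'
#' Draws random pathways over the supplied proteins, optionally prepending
#' planted pathways (e.g. one fully contained in a known differential set)
#' so enrichment recovery can be tested against ground truth.
#'
#' @param proteins background protein symbols.
#' @param n_pathways number of random pathways.
#' @param size_range min/max pathway size.
#' @param planted optional list of lists with fields `name`, `category`,
#'   `members`.
#' @param seed integer seed.
#' @param path optional file path; when given, a GMT file (name, category,
#'   members, tab-separated) is written and the path returned invisibly.
#' @return pathway annotation tibble as from [read_gmt()] (or the path).
#' @export
simulate_gmt <- function(proteins, n_pathways = 100, size_range = c(5, 25),
                         planted = NULL, seed = 1, path = NULL) {
  categories <- c("Immune System", "Signal Transduction", "Hemostasis",
                  "Extracellular matrix organization", "Metabolism",
                  "Metabolism of proteins", "Developmental Biology",
                  "Vesicle-mediated transport")
  rows <- with_substream(seed, "gmt", {
    lapply(seq_len(n_pathways), function(i) {
      size <- sample(seq(size_range[1], size_range[2]), 1)
      list(name = sprintf("Pathway_%03d", i),
           category = sample(categories, 1),
           members = sample(proteins, min(size, length(proteins))))
    })
  })
  rows <- c(planted, rows)
  ann <- tibble::tibble(
    pathway = vapply(rows, `[[`, "", "name"),
    top_name = vapply(rows, `[[`, "", "category"),
    members = lapply(rows, function(r) toupper(r$members))
  )
  if (anyDuplicated(ann$pathway)) stop("duplicate pathway names in simulation")
  if (!is.null(path)) {
    lines <- vapply(seq_len(nrow(ann)), function(i) {
      paste(c(ann$pathway[i], ann$top_name[i], ann$members[[i]]),
            collapse = "\t")
    }, "")
    writeLines(lines, path)
    return(invisible(path))
  }
  ann
}
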