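#' Planted-complex specification for the simulator
#'
#' @param name complex name.
#' @param n_members number of member proteins.
#' @param cognate character vector of knockout conditions in which the
#'   complex co-depletes.
#' @param residual residual fraction in (0, 1]: the members' expected
#'   knockout/wild-type ratio in cognate conditions (0.08 = 8% of wild-type
#'   level remains).
#' @return A `complex_spec` list.
#' @export
complex_spec <- function(name, n_members, cognate, residual) {
  n_members <- as.integer(n_members)
  if (n_members < 1L) nrf_validation_error("n_members must be positive")
  if (!is.numeric(residual) || residual <= 0 || residual > 1) {
    nrf_validation_error(paste0("residual must be in (0, 1] for complex ", name))
  }
  structure(list(name = as.character(name), n_members = n_members,
                 cognate = as.character(cognate), residual = residual),
            class = "complex_spec")
}

#' Simulator configuration
#'
#' Describes a multi-knockout SILAC chromosome-proteomics study: a handful of
#' knockout conditions with 2-3 biological replicates each, a few planted
#' complexes whose members co-deplete to a residual fraction in their cognate
#' knockouts, and a large hitchhiker background with broader, signal-free
#' ratio noise, plus missing values.
#'
#' @param n_proteins total proteins (members + hitchhikers).
#' @param conditions named integer vector: replicate count per condition.
#' @param complexes list of [complex_spec()]s; cognate conditions must be
#'   among `conditions`.
#' @param noise_sd log2-scale measurement noise for complex members
#'   (default 0.3).
#' @param hitchhiker_sd log2-scale noise for hitchhikers (default 0.5 —
#'   contaminant ratios in chromosome preparations are empirically more
#'   dispersed than those of structural proteins).
#' @param missing_rate probability a cell is unquantified, in `[0, 1)`
#'   (default 0.1). Uniform at random by default; `missing_bias = "low"`
#'   makes low-abundance (strongly depleted) cells more likely to drop out.
#' @param missing_bias `"uniform"` or `"low"`.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_proteins, conditions, complexes = list(),
                       noise_sd = 0.3, hitchhiker_sd = 0.5,
                       missing_rate = 0.1, missing_bias = c("uniform", "low"),
                       seed = 1) {
  missing_bias <- match.arg(missing_bias)
  n_proteins <- as.integer(n_proteins)
  conditions <- stats::setNames(as.integer(conditions), names(conditions))
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    nrf_validation_error("conditions must be a named vector of replicate counts")
  }
  if (any(conditions < 1L)) nrf_validation_error("replicate counts must be >= 1")
  for (cx in complexes) {
    if (!inherits(cx, "complex_spec")) {
      nrf_validation_error("complexes must be complex_spec objects")
    }
    unknown <- setdiff(cx$cognate, names(conditions))
    if (length(unknown)) {
      nrf_validation_error(sprintf("complex '%s' has unknown cognate condition(s): %s",
                                   cx$name, paste(unknown, collapse = ", ")))
    }
  }
  n_members <- sum(vapply(complexes, `[[`, integer(1), "n_members"))
  if (n_members > n_proteins) {
    nrf_validation_error("total complex members exceed n_proteins")
  }
  if (noise_sd < 0 || hitchhiker_sd < 0) {
    nrf_validation_error("noise_sd and hitchhiker_sd must be non-negative")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    nrf_validation_error("missing_rate must be in [0, 1)")
  }
  structure(list(n_proteins = n_proteins, conditions = conditions,
                 complexes = complexes, noise_sd = noise_sd,
                 hitchhiker_sd = hitchhiker_sd, missing_rate = missing_rate,
                 missing_bias = missing_bias, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a knockout-perturbation SILAC dataset
#'
#' Each protein's expected log2(knockout/wild-type) ratio is
#' `log2(residual)` in the cognate conditions of its complex and 0 elsewhere
#' (hitchhikers: 0 everywhere). Per-experiment values add Normal log2 noise
#' (`noise_sd` for members, `hitchhiker_sd` for hitchhikers), are exported as
#' ratios `2^value`, and are masked missing at `missing_rate`. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with `table` (a `quant_table`), `design`
#'   (an `experiment_design`, all `ko_over_wt`), and `truth` (a
#'   `ground_truth`: `membership` named vector, complex name or
#'   `"hitchhiker"`; `true_mean` proteins x conditions log2 expectation
#'   matrix).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  conds <- names(cfg$conditions)
  design <- experiment_design(
    experiment = unlist(lapply(conds, function(cc)
      sprintf("%s_r%d", cc, seq_len(cfg$conditions[[cc]])))),
    condition = rep(conds, cfg$conditions),
    replicate = unlist(lapply(cfg$conditions, seq_len)),
    orientation = "ko_over_wt"
  )
  membership <- character(0)
  ids <- character(0)
  for (cx in cfg$complexes) {
    m_ids <- sprintf("%s_M%02d", toupper(cx$name), seq_len(cx$n_members))
    ids <- c(ids, m_ids)
    membership <- c(membership, stats::setNames(rep(cx$name, cx$n_members), m_ids))
  }
  n_hh <- cfg$n_proteins - length(ids)
  if (n_hh > 0) {
    hh_ids <- sprintf("HH_%05d", seq_len(n_hh))
    ids <- c(ids, hh_ids)
    membership <- c(membership, stats::setNames(rep("hitchhiker", n_hh), hh_ids))
  }
  true_mean <- matrix(0, length(ids), length(conds),
                      dimnames = list(ids, conds))
  for (cx in cfg$complexes) {
    true_mean[membership == cx$name, cx$cognate] <- log2(cx$residual)
  }
  sd_per_protein <- ifelse(membership == "hitchhiker",
                           cfg$hitchhiker_sd, cfg$noise_sd)
  n_exp <- nrow(design)
  log2r <- true_mean[, design$condition, drop = FALSE] +
    matrix(stats::rnorm(length(ids) * n_exp, sd = rep(sd_per_protein, n_exp)),
           length(ids), n_exp)
  colnames(log2r) <- design$experiment
  if (cfg$missing_rate > 0) {
    p_miss <- if (cfg$missing_bias == "uniform") {
      matrix(cfg$missing_rate, length(ids), n_exp)
    } else {
      # low-abundance bias: dropout weight doubles per log2 unit of depletion,
      # rescaled so the mean rate stays missing_rate
      w <- 2^pmax(0, -log2r)
      cfg$missing_rate * w * length(w) / sum(w)
    }
    mask <- matrix(stats::runif(length(log2r)) < pmin(p_miss, 1),
                   length(ids), n_exp)
    log2r[mask] <- NA_real_
  }
  proteins <- data.frame(
    protein_id = ids,
    gene_name = ids,
    is_reverse = FALSE,
    is_contaminant = FALSE,
    stringsAsFactors = FALSE
  )
  truth <- structure(list(membership = membership, true_mean = true_mean),
                     class = "ground_truth")
  list(table = quant_table(proteins, 2^log2r), design = design, truth = truth)
}

#' Study-scale default simulator configuration
#'
#' Emulates a five-knockout mitotic-chromosome SILAC panel: conditions SMC2,
#' CAP-H, CAP-D3 (2 replicates each), Scc1 (3 replicates), and SMC5
#' (2 replicates) — 11 experiments — over 5,058 detected proteins. Planted
#' complexes follow the depletion structure such a panel reports: condensin I
#' co-depleting in SMC2 and CAP-H knockouts, condensin II in SMC2 and
#' CAP-D3, cohesin in Scc1 (residual 0.2, within the 15-27% range of core
#' cohesin subunits), the SMC5/6 complex in SMC5 (residual 0.08), and a
#' chromosome passenger complex co-depleting with condensin I.
#'
#' @param seed RNG seed (default 1).
#' @param noise_sd member noise, log2 scale (default 0.3).
#' @return A [sim_config()].
#' @export
default_paper_like_config <- function(seed = 1, noise_sd = 0.3) {
  sim_config(
    n_proteins = 5058,
    conditions = c(SMC2 = 2L, `CAP-H` = 2L, `CAP-D3` = 2L, Scc1 = 3L, SMC5 = 2L),
    complexes = list(
      complex_spec("condensin_I", 5, c("SMC2", "CAP-H"), 0.25),
      complex_spec("condensin_II", 5, c("SMC2", "CAP-D3"), 0.30),
      complex_spec("cohesin", 6, "Scc1", 0.20),
      complex_spec("SMC5_6", 6, "SMC5", 0.08),
      complex_spec("CPC", 4, c("SMC2", "CAP-H"), 0.35)
    ),
    noise_sd = noise_sd,
    hitchhiker_sd = 0.5,
    missing_rate = 0.1,
    seed = seed
  )
}

#' Build training sets from simulation ground truth
#'
#' For each planted complex, takes a fraction of its members as training
#' positives (withholding the rest as recoverable "novel" members) and
#' samples a shared negative set from the hitchhiker background — standing in
#' for the curated cytoplasmic/contaminant list used with real data.
#'
#' @param truth a `ground_truth` from [simulate_dataset()].
#' @param holdout_fraction fraction of each complex's members withheld from
#'   training (default 0).
#' @param n_negatives size of the shared negative set (default 50).
#' @param seed RNG seed for the negative sample and holdout choice.
#' @return List with `sets` (named list of `training_set`s) and `withheld`
#'   (named list of withheld member IDs per complex).
#' @export
training_sets_from_truth <- function(truth, holdout_fraction = 0,
                                     n_negatives = 50, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (holdout_fraction < 0 || holdout_fraction >= 1) {
    nrf_validation_error("holdout_fraction must be in [0, 1)")
  }
  set.seed(seed)
  hh <- names(truth$membership)[truth$membership == "hitchhiker"]
  if (length(hh) < n_negatives) {
    nrf_validation_error("not enough hitchhikers to sample negatives from")
  }
  negatives <- sort(sample(hh, n_negatives))
  cxs <- setdiff(unique(truth$membership), "hitchhiker")
  sets <- list()
  withheld <- list()
  for (cx in cxs) {
    members <- names(truth$membership)[truth$membership == cx]
    n_hold <- floor(holdout_fraction * length(members))
    hold <- if (n_hold > 0) sort(sample(members, n_hold)) else character(0)
    sets[[cx]] <- training_set(cx, setdiff(members, hold), negatives)
    withheld[[cx]] <- hold
  }
  list(sets = sets, withheld = withheld)
}

#' Write ground truth as TSV
#' @param truth a `ground_truth`.
#' @param path output file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- data.frame(protein_id = names(truth$membership),
                    membership = unname(truth$membership),
                    stringsAsFactors = FALSE)
  for (cond in colnames(truth$true_mean)) {
    out[[paste0("true_log2_", cond)]] <- fmt_num(truth$true_mean[, cond])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a simulator configuration from YAML
#'
#' Schema: `n_proteins`, `conditions` (mapping condition -> replicate count),
#' `complexes` (list of mappings with `name`, `n_members`, `cognate`,
#' `residual`), and optional `noise_sd`, `hitchhiker_sd`, `missing_rate`,
#' `missing_bias`, `seed`.
#'
#' @param path YAML file path.
#' @param seed optional seed override.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  if (!file.exists(path)) nrf_io_error(paste0("sim config not found: ", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$n_proteins) || is.null(y$conditions)) {
    nrf_validation_error("sim config needs n_proteins and conditions")
  }
  complexes <- lapply(y$complexes %||% list(), function(cx) {
    complex_spec(cx$name, cx$n_members, unlist(cx$cognate), cx$residual)
  })
  sim_config(
    n_proteins = y$n_proteins,
    conditions = unlist(y$conditions),
    complexes = complexes,
    noise_sd = y$noise_sd %||% 0.3,
    hitchhiker_sd = y$hitchhiker_sd %||% 0.5,
    missing_rate = y$missing_rate %||% 0.1,
    missing_bias = y$missing_bias %||% "uniform",
    seed = seed %||% y$seed %||% 1
  )
}
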