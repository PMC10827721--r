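#' Build a full-factorial RNA-seq sample design
#'
#' Constructs the sample sheet for a plant-inoculation time-course experiment:
#' every combination of condition and timepoint, replicated `n_reps` times.
#' The default layout is 3 conditions x 3 timepoints x 3 replicates = 27
#' libraries (control and two fungal treatment arms sampled at 48, 72 and
#' 96 hours post inoculation).
#'
#' @param n_reps replicates per condition/timepoint cell; at least 2 (a single
#'   replicate leaves within-group dispersion undefined downstream).
#' @param timepoints numeric vector of sampling times (hours).
#' @param conditions character vector of arm names; the first is conventionally
#'   the control.
#' @return A data.frame with columns `sample_id` (`<condition>_<timepoint>_r<rep>`),
#'   `condition` (factor with levels in the given order), `timepoint`,
#'   `replicate`.
#' @examples
#' design <- make_design()
#' nrow(design) # 27
#' @export
make_design <- function(n_reps = 3, timepoints = c(48, 72, 96),
                        conditions = c("control", "treatA", "treatB")) {
  if (length(n_reps) != 1 || is.na(n_reps) || n_reps < 2) {
    stop("n_reps must be a single integer >= 2")
  }
  if (length(timepoints) == 0 || length(conditions) == 0) {
    stop("timepoints and conditions must be non-empty")
  }
  if (anyDuplicated(timepoints) || anyDuplicated(conditions)) {
    stop("timepoints and conditions must be unique")
  }
  grid <- expand.grid(replicate = seq_len(n_reps), timepoint = timepoints,
                      condition = conditions, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  design <- data.frame(
    sample_id = sprintf("%s_%s_r%d", grid$condition, grid$timepoint, grid$replicate),
    condition = factor(grid$condition, levels = conditions),
    timepoint = grid$timepoint,
    replicate = as.integer(grid$replicate),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(design$sample_id))
  design
}

#' Parameters for the synthetic count generator
#'
#' Bundles and validates the knobs of [simulate_experiment()]. Gene-wise
#' baseline log-means are Gaussian; within-module correlation is induced by a
#' shared latent factor per module and sample whose loading `module_loading`
#' maps monotonically to the within-module Spearman correlation; planted hubs
#' receive the larger `hub_loading`. Counts are negative binomial with
#' variance `mu + dispersion * mu^2`.
#'
#' @param n_genes total number of genes.
#' @param module_sizes sizes of planted co-expression modules (each >= 2,
#'   summing to at most `n_genes`); remaining genes are uncorrelated background.
#' @param module_loading latent-factor loading in `[0, 1]` for ordinary module
#'   members.
#' @param hub_per_module planted hubs per module (first genes of each module).
#' @param hub_loading loading for planted hubs; must be >= `module_loading`.
#' @param de_fraction fraction of genes planted as differentially expressed.
#' @param de_logfc true absolute log2 fold change of planted DE genes.
#' @param baseline_logmean_mean,baseline_logmean_sd mean and sd of the
#'   natural-log baseline expression level.
#' @param dispersion negative-binomial dispersion phi (> 0).
#' @param libsize_range range of the uniform per-library depth factor.
#' @param seed integer RNG seed; the same seed reproduces counts bit-identically.
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(n_genes = 2000,
                             module_sizes = c(150, 120, 100),
                             module_loading = 0.8,
                             hub_per_module = 5,
                             hub_loading = 0.95,
                             de_fraction = 0.05,
                             de_logfc = 2,
                             baseline_logmean_mean = 5.5,
                             baseline_logmean_sd = 1,
                             dispersion = 0.04,
                             libsize_range = c(0.7, 1.3),
                             seed = 1) {
  if (n_genes < 1) stop("n_genes must be positive")
  if (length(module_sizes) > 0) {
    if (any(module_sizes < 2)) stop("each module must have at least 2 genes")
    if (sum(module_sizes) > n_genes) stop("module_sizes sum exceeds n_genes")
  }
  if (module_loading < 0 || module_loading > 1) stop("module_loading must be in [0, 1]")
  if (hub_per_module < 0) stop("hub_per_module must be non-negative")
  if (length(module_sizes) > 0 && hub_per_module > min(module_sizes)) {
    stop("hub_per_module exceeds the smallest module")
  }
  if (hub_loading < module_loading) stop("hub_loading must be >= module_loading")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]")
  if (de_logfc <= 0) stop("de_logfc must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (length(libsize_range) != 2 || any(libsize_range <= 0) ||
      libsize_range[1] > libsize_range[2]) {
    stop("libsize_range must be an increasing pair of positive reals")
  }
  structure(list(
    n_genes = as.integer(n_genes), module_sizes = as.integer(module_sizes),
    module_loading = module_loading, hub_per_module = as.integer(hub_per_module),
    hub_loading = hub_loading, de_fraction = de_fraction, de_logfc = de_logfc,
    baseline_logmean_mean = baseline_logmean_mean,
    baseline_logmean_sd = baseline_logmean_sd, dispersion = dispersion,
    libsize_range = libsize_range, seed = as.integer(seed)
  ), class = "generator_params")
}

#' Simulate an RNA-seq count matrix with planted structure
#'
#' Generates negative-binomial counts over a full-factorial design with three
#' kinds of planted signal, so that every downstream stage (differential
#' expression, co-expression network inference, community detection, hub
#' scoring) can be validated against known ground truth:
#'
#' * **Co-expression modules.** Genes in module *m* share a latent Gaussian
#'   factor `z[m, s] ~ N(0, 1)` per sample; gene *g*'s natural-log mean is
#'   `b_g + lambda_g * z[m, s]` with `b_g ~ N(baseline_logmean_mean, sd)` and
#'   loading `lambda_g` equal to `hub_loading` for planted hubs,
#'   `module_loading` for other members, 0 for background genes.
#' * **Differential expression.** A fraction `de_fraction` of genes receives a
#'   signed shift of `de_logfc * log(2)` on the log-mean in the treated arm(s)
#'   of its contrast; DE genes are split evenly between arm-A-only,
#'   arm-B-only, and both-arms (yielding non-trivial Venn partitions).
#' * **Library depth.** Each sample's mean is scaled by
#'   `L_s ~ Uniform(libsize_range)`; counts are
#'   `NB(mean = L_s * exp(logmean), dispersion)`.
#'
#' The generator is deterministic: the same `params$seed` yields bit-identical
#' counts and truth. The caller's RNG state is left untouched.
#'
#' @param design sample sheet from [make_design()]; the first condition level
#'   is treated as the control arm.
#' @param params a [generator_params()] object.
#' @return A list of class `sim_experiment` with elements `counts` (integer
#'   matrix, genes x samples), `design`, and `truth` — a list with
#'   `module_of` (named vector, `NA` for background), `hub_genes` (list per
#'   module), and `de` (data.frame `gene_id`, `condition`, `logfc` with the
#'   signed true log2 fold change per planted contrast).
#' @export
simulate_experiment <- function(design, params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  if (!all(c("sample_id", "condition", "timepoint", "replicate") %in% names(design))) {
    stop("design must come from make_design()")
  }
  conds <- levels(design$condition)
  treated <- conds[-1]
  n_genes <- params$n_genes
  n_samples <- nrow(design)
  genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))

  n_mod <- length(params$module_sizes)
  module_of <- rep(NA_integer_, n_genes)
  if (n_mod > 0) {
    module_of[seq_len(sum(params$module_sizes))] <-
      rep(seq_len(n_mod), params$module_sizes)
  }
  names(module_of) <- genes
  hub_genes <- lapply(seq_len(n_mod), function(m) {
    members <- genes[which(module_of == m)]
    members[seq_len(min(params$hub_per_module, length(members)))]
  })
  lambda <- rep(0, n_genes)
  lambda[!is.na(module_of)] <- params$module_loading
  lambda[genes %in% unlist(hub_genes)] <- params$hub_loading

  out <- with_seed(params$seed, {
    b <- stats::rnorm(n_genes, params$baseline_logmean_mean,
                      params$baseline_logmean_sd)
    z <- if (n_mod > 0) {
      matrix(stats::rnorm(n_mod * n_samples), n_mod, n_samples)
    } else matrix(0, 0, n_samples)

    n_de <- round(params$de_fraction * n_genes)
    de_genes <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
    # arm assignment 0 = first treated arm only, 1 = second only, 2 = both;
    # with a single treated arm everything lands there
    de_arm <- if (length(treated) >= 2) {
      sample(0:2, n_de, replace = TRUE)
    } else rep(0L, n_de)

    in_arm <- function(i, arm_label) {
      a <- de_arm[i]
      if (a == 2L) TRUE else treated[a + 1L] == arm_label
    }
    de_tab <- if (n_de > 0) {
      rows <- do.call(rbind, lapply(seq_len(n_de), function(i) {
        arms <- treated[vapply(treated, function(tr) in_arm(i, tr), logical(1))]
        data.frame(gene_id = genes[de_genes[i]], condition = arms,
                   logfc = de_sign[i] * params$de_logfc,
                   stringsAsFactors = FALSE)
      }))
      rownames(rows) <- NULL
      rows
    } else {
      data.frame(gene_id = character(0), condition = character(0),
                 logfc = numeric(0))
    }

    logmean <- matrix(b, n_genes, n_samples)
    if (n_mod > 0) {
      in_mod <- !is.na(module_of)
      logmean[in_mod, ] <- logmean[in_mod, , drop = FALSE] +
        lambda[in_mod] * z[module_of[in_mod], , drop = FALSE]
    }
    if (n_de > 0) {
      for (i in seq_len(n_de)) {
        s_in <- as.character(design$condition) %in%
          treated[vapply(treated, function(tr) in_arm(i, tr), logical(1))]
        logmean[de_genes[i], s_in] <- logmean[de_genes[i], s_in] +
          de_sign[i] * params$de_logfc * log(2)
      }
    }

    L <- stats::runif(n_samples, params$libsize_range[1], params$libsize_range[2])
    mu <- sweep(exp(logmean), 2, L, `*`)
    counts <- matrix(
      stats::rnbinom(n_genes * n_samples, mu = mu, size = 1 / params$dispersion),
      n_genes, n_samples, dimnames = list(genes, design$sample_id)
    )
    storage.mode(counts) <- "integer" 
    list(counts = counts, de_tab = de_tab)
  })

  structure(list(
    counts = out$counts,
    design = design,
    truth = list(module_of = module_of, hub_genes = hub_genes, de = out$de_tab),
    params = params
  ), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment: %d genes x %d samples, %d modules, %d planted DE genes>\n",
              nrow(x$counts), ncol(x$counts), length(x$params$module_sizes),
              length(unique(x$truth$de$gene_id))))
  invisible(x)
}
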