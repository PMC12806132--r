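#' Describe a synthetic multi-omic study design
#'
#' The generator emulates the structure of a tissue cohort feeding the
#' flux pipeline: a toy metabolic network of parallel, substitutable
#' pathways between a shared carbon source and a growth sink, and
#' multi-omic layers (transcript, copy-number, protein) with planted
#' class-discriminative structure, nuisance features and optional class
#' imbalance. All randomness derives from `seed`.
#'
#' @param n_pathways Number of parallel pathways (subsystems).
#' @param reactions_per_pathway Chain length of each pathway.
#' @param genes_per_reaction 1..3; controls the GPR forms used (single
#'   gene; complex `and`; isozyme `or` mixing both).
#' @param classes Named integer vector of per-class sample counts
#'   (>= 4 each), e.g. `c(N = 30, C = 30)`; unequal counts encode class
#'   imbalance.
#' @param planted_effects data.frame with columns `class`, `pathway`
#'   (e.g. `"PW1"`), `direction` (`"up"`/`"down"`) and `multiplier`
#'   (> 0) applied to that pathway's transcript levels in that class;
#'   `NULL` for a null design.
#' @param noise_sd Multiplicative log-normal noise sd on transcript and
#'   protein values.
#' @param gx_shift In `[0, 1]`: strength of the copy-number bias of the
#'   planted GX marker genes (0 = null).
#' @param n_nuisance_genes Uninformative extra genes in TX/GX.
#' @param n_gx_markers Planted class-biased copy-number genes.
#' @param seed Integer seed.
#' @return A validated `synthetic_design` list.
#' @export
synthetic_design <- function(n_pathways = 4, reactions_per_pathway = 5,
                             genes_per_reaction = 2,
                             classes = c(N = 30, C = 30),
                             planted_effects = data.frame(
                               class = "C", pathway = "PW1",
                               direction = "down", multiplier = 0.2,
                               stringsAsFactors = FALSE),
                             noise_sd = 0.3, gx_shift = 0.8,
                             n_nuisance_genes = 40, n_gx_markers = 10,
                             seed = 1) {
  stopifnot(n_pathways >= 1, reactions_per_pathway >= 1,
            genes_per_reaction %in% 1:3)
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    stop("classes must be a named vector of sample counts", call. = FALSE)
  }
  if (any(classes < 4)) {
    stop("each class needs at least 4 samples", call. = FALSE)
  }
  if (!is.null(planted_effects)) {
    stopifnot(all(c("class", "pathway", "direction", "multiplier") %in%
                    names(planted_effects)))
    if (any(planted_effects$multiplier <= 0)) {
      stop("effect multipliers must be > 0", call. = FALSE)
    }
    if (any(!planted_effects$class %in% names(classes))) {
      stop("planted effect references unknown class", call. = FALSE)
    }
  }
  structure(list(
    n_pathways = n_pathways,
    reactions_per_pathway = reactions_per_pathway,
    genes_per_reaction = genes_per_reaction,
    classes = classes,
    planted_effects = planted_effects,
    noise_sd = noise_sd,
    gx_shift = gx_shift,
    n_nuisance_genes = n_nuisance_genes,
    n_gx_markers = n_gx_markers,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' Build the toy metabolic model of a synthetic design
#'
#' `n_pathways` parallel linear chains convert a shared intracellular
#' carbon hub into one growth precursor consumed by the objective
#' reaction, so the optimal growth rate is the *sum* of the pathway
#' capacities and down-regulating one pathway lowers only its own
#' reactions' fluxes. Each pathway is its own subsystem; its reactions
#' carry GPR rules cycling through single-gene, complex (`and`) and
#' isozyme (`or`) forms. The glucose exchange and the hub transporter
#' are reversible so irreversibilization is exercised. Feasibility with
#' all-ones expression is asserted at build time.
#'
#' @param design A `synthetic_design`.
#' @return A `metabolic_model`.
#' @export
make_toy_model <- function(design) {
  P <- design$n_pathways
  R <- design$reactions_per_pathway
  gpr_forms <- function(p, r) {
    g <- function(i) sprintf("PW%d_R%d_g%d", p, r, i)
    k <- design$genes_per_reaction
    form <- (r - 1L) %% 3L
    if (k == 1 || form == 0) return(g(1))
    if (k == 2) {
      if (form == 1) return(sprintf("%s and %s", g(1), g(2)))
      return(sprintf("%s or %s", g(1), g(2)))
    }
    if (form == 1) return(sprintf("%s and %s", g(1), g(2)))
    sprintf("(%s and %s) or %s", g(1), g(2), g(3))
  }
  mets <- data.frame(id = c("glc_e", "glc_c", "pre_c"),
                     name = c("glucose (extracellular)",
                              "glucose (cytosol)", "growth precursor"),
                     compartment = c("e", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_glc", stoichiometry = c(glc_e = -1),
         lower_bound = -1000, upper_bound = 1000,
         subsystem = "Exchange", gpr = NULL),
    list(id = "GLCt", stoichiometry = c(glc_e = -1, glc_c = 1),
         lower_bound = -1000, upper_bound = 1000,
         subsystem = "Transport", gpr = NULL)
  )
  for (p in seq_len(P)) {
    sub <- sprintf("PW%d", p)
    prev <- "glc_c"
    for (r in seq_len(R)) {
      nxt <- if (r == R) "pre_c" else sprintf("m_p%d_%d", p, r)
      if (nxt != "pre_c" && !nxt %in% mets$id) {
        mets <- rbind(mets, data.frame(id = nxt, name = nxt,
                                       compartment = "c",
                                       stringsAsFactors = FALSE))
      }
      st <- stats::setNames(c(-1, 1), c(prev, nxt))
      rxns[[length(rxns) + 1L]] <- list(
        id = sprintf("PW%d_R%d", p, r), stoichiometry = st,
        lower_bound = 0, upper_bound = 1000, subsystem = sub,
        gpr = parse_gpr(gpr_forms(p, r)))
      prev <- nxt
    }
  }
  rxns[[length(rxns) + 1L]] <- list(
    id = "GROWTH", stoichiometry = c(pre_c = -1),
    lower_bound = 0, upper_bound = 1000, subsystem = "Biomass", gpr = NULL)
  model <- metabolic_model(mets, rxns, "GROWTH", id = "toy_model")
  # feasibility guarantee: all-ones expression must allow growth
  irr <- make_irreversible(model)$model
  ones <- stats::setNames(rep(1, length(model_genes(model))),
                          model_genes(model))
  con <- assign_eflux_bounds(irr, ones, vmax = 1000,
                             medium = toy_medium(model))
  sol <- solve_fba(con$model)
  if (sol$status != "optimal" || sol$objective <= 0) {
    stop("internal error: toy model infeasible under all-ones expression",
         call. = FALSE)
  }
  model
}

#' Medium specification for the toy model
#'
#' Opens every exchange reaction of the toy network for uptake. The
#' default limit (1000) is deliberately non-limiting: in the synthetic
#' world transcription must be the binding resource, otherwise
#' expression-capped bounds could never shape the flux distribution
#' (see the methods vignette).
#'
#' @param model The toy `metabolic_model`.
#' @param uptake_limit Uptake cap per exchange (default 1000).
#' @return A `medium_spec`.
#' @export
toy_medium <- function(model, uptake_limit = 1000) {
  medium_spec(exchange_reactions(model), uptake_limit = uptake_limit)
}

stage_strength <- c(S1 = 0.5, S2 = 0.75, S3 = 0.9, S4 = 1)

#' Generate a synthetic multi-omic cohort
#'
#' Produces transcript (`TX`), copy-number (`GX`) and protein (`PX`)
#' matrices plus sample metadata for a toy model:
#' \itemize{
#'   \item TX: per-gene log-normal baselines (meanlog 3, sdlog 0.8 — an
#'     FPKM-like stand-in), multiplicative per-sample noise, a
#'     constitutively high reference gene (`PKM`) and low-level nuisance
#'     genes; planted effects multiply the target pathway's genes in the
#'     stated class, attenuated by stage (S1 weakest) so early-stage
#'     differences are subtler than cancer/normal ones.
#'   \item GX: integer copy numbers 0..4, baseline centred on 2;
#'     planted marker genes are amplification-biased in non-normal
#'     classes with strength `gx_shift` (a signal independent of TX).
#'   \item PX: protein abundances for half of the model genes,
#'     proportional to TX with extra independent noise, plus nuisance
#'     proteins.
#' }
#' Same seed, same matrices, bit for bit.
#'
#' @param design A `synthetic_design`.
#' @param model The matching toy model from [make_toy_model()].
#' @return List with `tx`, `gx`, `px` (`omic_matrix` objects) and
#'   `metadata` (data.frame: `sample_id`, `condition`, `subtype`,
#'   `stage`).
#' @export
make_cohort <- function(design, model) {
  with_seed(design$seed, {
    classes <- design$classes
    sample_ids <- unlist(lapply(names(classes), function(cl) {
      sprintf("%s_%03d", cl, seq_len(classes[[cl]]))
    }))
    cls <- rep(names(classes), classes)
    condition <- ifelse(cls == "N", "N", "C")
    stage <- rep(NA_character_, length(cls))
    is_c <- condition == "C"
    stage[is_c] <- sample(names(stage_strength), sum(is_c), replace = TRUE,
                          prob = c(0.4, 0.3, 0.2, 0.1))
    metadata <- data.frame(sample_id = sample_ids, condition = condition,
                           subtype = cls, stage = stage,
                           stringsAsFactors = FALSE)

    mgenes <- model_genes(model)
    nuis <- sprintf("NUIS_g%03d", seq_len(design$n_nuisance_genes))
    genes <- c(mgenes, nuis, "PKM")
    base <- stats::rlnorm(length(genes), meanlog = 3, sdlog = 0.8)
    names(base) <- genes
    base[nuis[seq_len(min(5, length(nuis)))]] <- 0.05  # near-floor genes
    base["PKM"] <- exp(3 + 3 * 0.8)                    # constitutive high
    n <- length(sample_ids)
    noise <- matrix(exp(stats::rnorm(length(genes) * n, 0,
                                     design$noise_sd)),
                    length(genes), n)
    tx <- base * noise
    dimnames(tx) <- list(genes, sample_ids)
    tx["PKM", ] <- base["PKM"]                         # stable reference
    sub_idx <- subsystem_index(model)
    if (!is.null(design$planted_effects)) {
      for (i in seq_len(nrow(design$planted_effects))) {
        eff <- design$planted_effects[i, ]
        rids <- sub_idx[[eff$pathway]]
        if (is.null(rids)) stop("planted effect targets unknown pathway: ",
                                eff$pathway, call. = FALSE)
        pg <- unique(unlist(lapply(model$reactions[rids],
                                   function(r) gpr_genes(r$gpr))))
        target <- which(cls == eff$class)
        mult <- eff$multiplier
        if (eff$direction == "up" && mult < 1) mult <- 1 / mult
        if (eff$direction == "down" && mult > 1) mult <- 1 / mult
        for (s in target) {
          str_ <- if (is.na(stage[s])) 1 else stage_strength[[stage[s]]]
          tx[pg, s] <- tx[pg, s] * exp(log(mult) * str_)
        }
      }
    }

    gxm <- sprintf("GXM_g%03d", seq_len(design$n_gx_markers))
    gx_genes <- c(mgenes, nuis, gxm)
    p0 <- c(0.05, 0.2, 0.5, 0.2, 0.05)                 # diploid-centred
    p1 <- c(0.02, 0.08, 0.20, 0.35, 0.35)              # amplified
    gx <- matrix(0L, length(gx_genes), n,
                 dimnames = list(gx_genes, sample_ids))
    for (g in seq_along(gx_genes)) {
      gx[g, ] <- sample(0:4, n, replace = TRUE, prob = p0)
    }
    shift <- design$gx_shift
    if (shift > 0) {
      pm <- (1 - shift) * p0 + shift * p1
      for (g in gxm) {
        amp <- sample(0:4, sum(is_c), replace = TRUE, prob = pm)
        gx[g, is_c] <- amp
      }
    }

    prot_genes <- mgenes[seq_len(ceiling(length(mgenes) / 2))]
    nuis_prot <- sprintf("NUISP_p%02d", 1:10)
    px_ids <- c(prot_genes, nuis_prot)
    px <- matrix(0, length(px_ids), n, dimnames = list(px_ids, sample_ids))
    px[prot_genes, ] <- tx[prot_genes, ] * 0.5 *
      exp(stats::rnorm(length(prot_genes) * n, 0, design$noise_sd))
    px[nuis_prot, ] <- stats::rlnorm(length(nuis_prot) * n,
                                     meanlog = 2, sdlog = 0.8)

    list(tx = omic_matrix(tx, "TX"),
         gx = omic_matrix(gx + 0, "GX"),
         px = omic_matrix(px, "PX"),
         metadata = metadata)
  })
}
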