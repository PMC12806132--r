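# Independent oracles used by the unit and acceptance tests. These are
# deliberately written as naive brute-force implementations, sharing no
# code path with the package internals they check.

# --- GPR -------------------------------------------------------------------

# brute-force recursive minSum evaluation over the AST
oracle_gpr_eval <- function(node, values, missing_policy = "skip") {
  if (node$kind == "gene") {
    if (node$gene %in% names(values)) return(values[[node$gene]])
    return(if (missing_policy == "zero") 0 else NA_real_)
  }
  kid_vals <- c()
  for (ch in node$children) {
    v <- oracle_gpr_eval(ch, values, missing_policy)
    if (!is.na(v)) kid_vals <- c(kid_vals, v)
  }
  if (length(kid_vals) == 0) return(NA_real_)
  if (node$kind == "and") return(min(kid_vals))
  sum(kid_vals)
}

# random AST with bounded depth and gene pool
random_gpr_ast <- function(depth_max = 5, genes = paste0("g", 1:12)) {
  build <- function(d) {
    if (d >= depth_max || stats::runif(1) < 0.4) {
      return(structure(list(kind = "gene", gene = sample(genes, 1)),
                       class = "gpr"))
    }
    k <- sample(2:3, 1)
    structure(list(kind = sample(c("and", "or"), 1),
                   children = lapply(seq_len(k), function(i) build(d + 1))),
              class = "gpr")
  }
  build(1)
}

# --- hypergeometric ---------------------------------------------------------

.small_primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43,
                   47, 53, 59)

# exponent of prime p in n! (Legendre's formula)
.legendre <- function(n, p) {
  e <- 0; q <- p
  while (q <= n) { e <- e + n %/% q; q <- q * p }
  e
}

# exact C(a, b) as a prime-exponent vector
.choose_exp <- function(a, b) {
  vapply(.small_primes, function(p)
    .legendre(a, p) - .legendre(b, p) - .legendre(a - b, p), numeric(1))
}

# exact rational evaluation of the hypergeometric tail P(X >= x):
# every term's binomials cancel exactly in integer exponent space; only
# the final per-term evaluation is floating point.
oracle_hypergeom_tail <- function(N, m, n, x) {
  if (x <= 0) return(1)
  hi <- min(m, n)
  if (x > hi) return(0)
  denom <- .choose_exp(N, n)
  total <- 0
  for (k in x:hi) {
    if ((n - k) > (N - m)) next
    e <- .choose_exp(m, k) + .choose_exp(N - m, n - k) - denom
    total <- total + prod(.small_primes^e)
  }
  total
}

# --- rank statistics --------------------------------------------------------

# exact two-sided Mann-Whitney p by enumerating all group assignments;
# U computed from pairwise comparisons, not ranks.
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(a, b) {
    sum(outer(a, b, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  u_obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  combs <- utils::combn(n, n1)
  u_all <- apply(combs, 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# step-up FDR adjustment, written as the literal definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# --- tree SHAP --------------------------------------------------------------

# cover-weighted conditional expectation of one tree given feature set S
# (0-based feature indices as stored in the fitted tree)
oracle_tree_expvalue <- function(tree, x, S, node = 1) {
  f <- tree$feature[node]
  if (f < 0) return(tree$val[node])
  if (f %in% S) {
    nxt <- if (x[f + 1] <= tree$threshold[node]) tree$left[node] + 1
           else tree$right[node] + 1
    return(oracle_tree_expvalue(tree, x, S, nxt))
  }
  l <- tree$left[node] + 1; r <- tree$right[node] + 1
  (tree$cover[l] * oracle_tree_expvalue(tree, x, S, l) +
     tree$cover[r] * oracle_tree_expvalue(tree, x, S, r)) / tree$cover[node]
}

# exact Shapley values of one tree by subset enumeration
oracle_tree_shap <- function(tree, x) {
  feats <- sort(unique(tree$feature[tree$feature >= 0]))
  M <- length(feats)
  phi <- numeric(length(x))
  for (fi in feats) {
    others <- setdiff(feats, fi)
    for (k in 0:length(others)) {
      combs <- if (k == 0) list(integer(0))
               else asplit(utils::combn(others, k), 2)
      for (S in combs) {
        S <- as.integer(S)
        w <- factorial(k) * factorial(M - k - 1) / factorial(M)
        phi[fi + 1] <- phi[fi + 1] +
          w * (oracle_tree_expvalue(tree, x, c(S, fi)) -
                 oracle_tree_expvalue(tree, x, S))
      }
    }
  }
  phi
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# --- fixtures ---------------------------------------------------------------

# linear chain EX -> A -> B -> biomass with configurable caps
chain_model <- function(ub1 = 10, ub2 = 5, ub3 = 1000) {
  metabolic_model(
    data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c",
               stringsAsFactors = FALSE),
    list(
      list(id = "EX_A", stoichiometry = c(A = 1), lower_bound = 0,
           upper_bound = ub1, subsystem = "Exchange", gpr = NULL),
      list(id = "AtoB", stoichiometry = c(A = -1, B = 1), lower_bound = 0,
           upper_bound = ub2, subsystem = "Core", gpr = NULL),
      list(id = "BIO", stoichiometry = c(B = -1), lower_bound = 0,
           upper_bound = ub3, subsystem = "Biomass", gpr = NULL)
    ),
    "BIO", id = "chain")
}

# two parallel capped routes feeding one sink
parallel_model <- function(ub1 = 3, ub2 = 4) {
  metabolic_model(
    data.frame(id = "A", name = "A", compartment = "c",
               stringsAsFactors = FALSE),
    list(
      list(id = "R1", stoichiometry = c(A = 1), lower_bound = 0,
           upper_bound = ub1, subsystem = "Core", gpr = NULL),
      list(id = "R2", stoichiometry = c(A = 1), lower_bound = 0,
           upper_bound = ub2, subsystem = "Core", gpr = NULL),
      list(id = "BIO", stoichiometry = c(A = -1), lower_bound = 0,
           upper_bound = 1000, subsystem = "Biomass", gpr = NULL)
    ),
    "BIO", id = "parallel")
}

# 5-reaction toy with one reversible reaction and GPRs on three
five_rxn_model <- function() {
  metabolic_model(
    data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
               compartment = "c", stringsAsFactors = FALSE),
    list(
      list(id = "EX_A", stoichiometry = c(A = 1), lower_bound = 0,
           upper_bound = 10, subsystem = "Exchange", gpr = NULL),
      list(id = "R1", stoichiometry = c(A = -1, B = 1), lower_bound = -10,
           upper_bound = 10, subsystem = "P1", gpr = parse_gpr("g1 and g2")),
      list(id = "R2", stoichiometry = c(B = -1, C = 1), lower_bound = -10,
           upper_bound = 10, subsystem = "P1", gpr = parse_gpr("g3 or g4")),
      list(id = "R3", stoichiometry = c(A = -1, C = 1), lower_bound = 0,
           upper_bound = 10, subsystem = "P2",
           gpr = parse_gpr("(g1 and g3) or g5")),
      list(id = "BIO", stoichiometry = c(C = -1), lower_bound = 0,
           upper_bound = 1000, subsystem = "Biomass", gpr = NULL)
    ),
    "BIO", id = "five")
}

# run a flux pipeline for one synthetic seed; small wrapper shared by
# planted-recovery tests
synthetic_flux_run <- function(seed, planted = TRUE) {
  des <- if (planted) synthetic_design(seed = seed)
         else synthetic_design(seed = seed, planted_effects = NULL,
                               gx_shift = 0)
  model <- make_toy_model(des)
  cohort <- make_cohort(des, model)
  nm <- normalize_reference_minmax(cohort$tx)
  irr <- make_irreversible(model)
  jx <- fluxome_for_cohort(irr$model, nm, medium = toy_medium(model))
  list(design = des, model = model, irr = irr$model, cohort = cohort,
       tx_norm = nm, jx = jx)
}
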