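## Shared fixtures, built in code.

## a desk-scale configuration for fast tests
smallSimConfig <- function(seed = 1L, ...) {
  args <- list(n_pairs_per_group = c(concordant = 15, typeA = 15,
                                     typeB = 15, intermediate = 15),
               n_dz_pairs = 10, n_genes = 400, n_signature_genes = 30,
               hdac_set_size = 20, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simConfig, args)
}

## build a TwinCohort directly from a per-individual trait table
makeCohort <- function(traits, pair, zygosity = "MZ", sex = "F", age = 50,
                       expr = NULL, fat_traits = NULL, lean_traits = NULL) {
  n <- nrow(traits)
  ind <- rownames(traits)
  cd <- data.frame(individual = ind, pair = pair,
                   zygosity = rep(zygosity, length.out = n),
                   sex = rep(sex, length.out = n),
                   age = rep(age, length.out = n),
                   traits, row.names = ind, check.names = FALSE)
  if (is.null(expr))
    expr <- matrix(numeric(0), 0, n, dimnames = list(NULL, ind))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expr), colData = S4Vectors::DataFrame(cd))
  obj <- new("TwinCohort", se)
  S4Vectors::metadata(obj)$traitNames <- colnames(traits)
  S4Vectors::metadata(obj)$fatTraits <- fat_traits
  S4Vectors::metadata(obj)$leanTraits <- lean_traits
  obj
}

## Jaccard index between two character sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

## independent brute-force oracle: plain running-sum ES by loop, with the
## same statistic definition (signed maximal deviation; an exact tie between
## the positive and negative extremum resolves by the sign of the summed
## running profile)
oracleES <- function(stats, members, weight = 1) {
  ord <- order(-stats, names(stats))
  s <- stats[ord]
  hit <- names(s) %in% members
  N <- length(s); n <- sum(hit)
  w <- abs(s)^weight
  nr <- sum(w[hit])
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) w[i] / nr else -1 / (N - n)
    run[i] <- acc
  }
  mx <- max(run); mn <- min(run)
  if (mx > -mn) mx else if (mx < -mn) mn
  else if (sum(run) >= 0) mx else mn
}


## planted-cohort fixture shared across tests (computed once per run)
plantedFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- smallSimConfig(seed = 42)
      co <- simulateExpression(cfg, simulateTwinCohort(cfg))
      orient <- assignReference(co)
      D <- traitDiscordance(co, orient)
      mzp <- names(zygosity(co))[zygosity(co) == "MZ"]
      v <- discordanceValues(D)
      Dmz <- new("DiscordanceMatrix",
                 values = v[rownames(v) %in% mzp, , drop = FALSE],
                 orientation = orientation(D), logBase = "e",
                 rejects = data.frame(pair = character(),
                                      feature = character(),
                                      reason = character()))
      cache <<- list(cfg = cfg, cohort = co, orient = orient, D = D,
                     Dmz = Dmz)
    }
    cache
  }
})

## bare DiscordanceMatrix around a pair x feature value matrix
mkAccD <- function(v) {
  new("DiscordanceMatrix", values = v,
      orientation = data.frame(pair = rownames(v), light = "x", heavy = "y"),
      logBase = "e")
}
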