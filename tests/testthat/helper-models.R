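# Shared builders and independent oracles for the test suite.

# one-variable linear decay dx/dt = -k x (closed form: x0 * exp(-k t))
decay_model <- function(k = 1, x0 = 1) {
  ode_model("decay",
            species = list(species("X", initial_amount = x0)),
            parameters = list(k = k),
            reactions = list(reaction("deg", reactants = c(X = 1L),
                                      kinetic_law = quote(k * X))))
}

# dx/dt = -(x - a): stable fixed point at a (affine, via a synthesis and a
# first-order decay reaction)
relax_model <- function(a = 2) {
  ode_model("relax",
            species = list(species("X", initial_amount = 0)),
            parameters = list(a = a),
            reactions = list(
              reaction("syn", products = c(X = 1L), kinetic_law = quote(a + 0 * X)),
              reaction("deg", reactants = c(X = 1L), kinetic_law = quote(X))))
}

# saddle d(x, y)/dt = (x, -y): growth of x, decay of y
saddle_model <- function() {
  ode_model("saddle",
            species = list(species("X", initial_amount = 0),
                           species("Y", initial_amount = 0)),
            parameters = list(),
            reactions = list(
              reaction("grow", products = c(X = 1L), kinetic_law = quote(X)),
              reaction("dec", reactants = c(Y = 1L), kinetic_law = quote(Y))))
}

# random small mass-action network for property tests
random_model <- function(seed, n_species = 4L, n_reactions = 5L) {
  set.seed(seed)
  ids <- paste0("S", seq_len(n_species))
  sp <- lapply(ids, function(i) species(i, initial_amount = runif(1, 0.1, 2)))
  pars <- setNames(as.list(runif(n_reactions, 0.1, 3)),
                   paste0("p", seq_len(n_reactions)))
  rx <- lapply(seq_len(n_reactions), function(r) {
    nr <- sample(0:2, 1)
    np <- sample(0:2, 1)
    reac <- if (nr > 0) table(sample(ids, nr, replace = TRUE)) else NULL
    prod <- if (np > 0) table(sample(ids, np, replace = TRUE)) else NULL
    law <- as.name(paste0("p", r))
    for (s in names(reac)) law <- call("*", law, as.name(s))
    reaction(paste0("r", r),
             reactants = if (is.null(reac)) integer() else
               setNames(as.integer(reac), names(reac)),
             products = if (is.null(prod)) integer() else
               setNames(as.integer(prod), names(prod)),
             kinetic_law = law)
  })
  ode_model(paste0("rand", seed), species = sp, parameters = pars,
            reactions = rx)
}

# brute-force rhs oracle: net stoichiometry times numerically evaluated law,
# independent of build_programme's expression assembly
oracle_rhs <- function(model, state) {
  env <- list2env(c(as.list(state),
                    Filter(function(v) !is.na(v), model$parameters)))
  for (nm in model$algebraic_order)
    assign(nm, eval(model$algebraic[[nm]], env), envir = env)
  out <- setNames(numeric(length(model$species)),
                  vapply(model$species, `[[`, character(1), "id"))
  for (r in model$reactions) {
    flux <- eval(r$kinetic_law, env)
    for (s in names(r$reactants)) out[[s]] <- out[[s]] - r$reactants[[s]] * flux
    for (s in names(r$products)) out[[s]] <- out[[s]] + r$products[[s]] * flux
  }
  const <- vapply(model$species, `[[`, logical(1), "constant")
  out[!const]
}

# random facet record for serialization property tests
random_record <- function(seed) {
  set.seed(seed)
  keys <- sample(facet_addresses(), sample(3:12, 1))
  slots <- lapply(keys, function(k) {
    anns <- if (runif(1) < 0.6)
      lapply(seq_len(sample(1:2, 1)), function(i)
        annotation(sample(c("uniprot", "obo.go", "taxonomy", "kisao"), 1),
                   paste0("ID", sample(1e5, 1)),
                   qualifier = sample(c("is", "isVersionOf"), 1)))
      else list()
    facet_slot(k,
               text = if (length(anns) == 0L || runif(1) < 0.7)
                 paste("note", sample(1e4, 1)),
               annotations = anns)
  })
  facet_record(paste0("model", seed), slots = slots,
               meta = global_meta(
                 origin = list(publication_id = as.character(sample(1e6, 1)),
                               authors = "A. Author", date = "2000-01"),
                 access = list(list(location = "file://x", format = "SBML")),
                 relations = if (runif(1) < 0.5)
                   list(list(other_model_id = "other",
                             relation_type = sample(c("abstraction",
                                                      "competing"), 1),
                             note = "n")) else list()))
}

# independent period oracle: autocorrelation of the post-transient series,
# first local maximum beyond zero lag, parabolic refinement
acf_period <- function(t, x) {
  dt <- t[2] - t[1]
  x <- x - mean(x)
  n <- length(x)
  ac <- stats::acf(x, lag.max = floor(n / 2), plot = FALSE)$acf[, 1, 1]
  # first local max after the initial decay through zero
  below <- which(ac < 0)[1]
  if (is.na(below)) return(NA_real_)
  # dominant periodicity: global acf maximum beyond the first zero crossing
  k <- below + which.max(ac[below:(length(ac) - 1)]) - 1
  if (k <= 1 || k >= length(ac)) return(NA_real_)
  a <- ac[k - 1]; b <- ac[k]; c <- ac[k + 1]
  off <- if (abs(a - 2 * b + c) > 0) 0.5 * (a - c) / (a - 2 * b + c) else 0
  (k - 1 + off) * dt
}

# session-cached fixture bundles (regime search is seeded but not free)
bundle1 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- tyson_model1()
    val
  }
})
bundle2 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- tyson_model2()
    val
  }
})
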