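# small dataset builders shared across tests

cls_data <- function(n = 40, p = 50, k = 2, sep = 3, seed = 1, classes = 2) {
  generate_classification(n_samples = n, n_features = p, n_informative = k,
                          n_classes = classes, separation = sep, seed = seed)
}

surv_data <- function(n = 60, p = 40, k = 2, eff = 1, cens = 0.3, seed = 1) {
  generate_survival(n_samples = n, n_features = p, n_informative = k,
                    effect_size = eff, censoring = cens, seed = seed)
}

# two cheap objectives for GA tests
cheap_objectives <- function(cap = 50, B = 30) {
  list(objective_classification(learner_nb(), B = B),
       objective_parsimony(cap = cap))
}

# a deterministic synthetic objective whose holdout fitness is the inner
# fitness minus a constant: controlled overestimation for pipeline tracing
const_overest_objective <- function(delta, name = "synthetic_metric") {
  base_fitness <- function(fs) {
    # deterministic, feature-dependent, in [delta, 1]
    v <- 0.3 + 0.5 * (sum(fs$indices) %% 97) / 96 + 0.1 / (1 + length(fs$indices))
    min(max(v, delta), 1)
  }
  obj <- moadjust::objective_parsimony(cap = 100, name = name)
  obj$kind <- "model_metric"
  obj$evaluator <- function(fs, data, seed) {
    list(fitness = base_fitness(fs), sd = 0.01, n_features = length(fs$indices))
  }
  obj$holdout_eval <- function(fs, train_data, test_data) {
    base_fitness(fs) - delta
  }
  attr(obj, "base_fitness") <- base_fitness
  obj
}
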