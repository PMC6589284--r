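# Genetic-algorithm feature selection with joint RBF-SVM hyperparameter
# tuning, and the two-stage classification cascade built on it. A
# chromosome is a bit string g1|g2|g3: g1 and g2 decode linearly to the SVM
# penalty C and the RBF width gamma; g3 is used directly as the feature
# mask. Fitness is the validation accuracy of the decoded SVM. Selection is
# fitness-proportional (roulette wheel), crossover is single-point applied
# separately to the parameter region g1|g2 and the mask region g3, mutation
# flips each bit independently, and the top chromosomes are carried over
# unchanged (elitism). The quadratic-program SVM solver is delegated to
# libsvm (e1071).

#' GA configuration
#'
#' Defaults follow the reference settings: population 100, 100 generations,
#' crossover probability 0.80, mutation probability 0.06, elitism rate 0.05,
#' 20 bits each for C and gamma. The parameter ranges are not stated by the
#' reference and default to C in `[0.01, 10000]`, gamma in `[1e-4, 10]`
#' (linear decoding); both are configurable and recorded in run records.
#'
#' @param population_size chromosomes per generation.
#' @param generations number of generations.
#' @param p_crossover single-point crossover probability per region.
#' @param p_mutation per-bit flip probability.
#' @param elitism_rate fraction of the population copied unchanged
#'   (realized as the top `ceiling(rate * size)`).
#' @param n_C,n_gamma bits encoding C and gamma.
#' @param n_f feature-mask length; defaults to the number of feature columns
#'   at fitness time when `NULL`.
#' @param C_range,gamma_range decoding ranges `(Pmin, Pmax)`.
#' @param seed integer seed.
#' @return a `ga_config` object.
#' @export
ga_config <- function(population_size = 100, generations = 100,
                      p_crossover = 0.80, p_mutation = 0.06,
                      elitism_rate = 0.05, n_C = 20, n_gamma = 20,
                      n_f = NULL, C_range = c(0.01, 10000),
                      gamma_range = c(1e-4, 10), seed = 1) {
  stopifnot(population_size >= 2, generations >= 0,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            elitism_rate >= 0, elitism_rate < 1,
            n_C >= 1, n_gamma >= 1,
            C_range[2] > C_range[1], gamma_range[2] > gamma_range[1])
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         p_crossover = p_crossover, p_mutation = p_mutation,
         elitism_rate = elitism_rate, n_C = as.integer(n_C),
         n_gamma = as.integer(n_gamma),
         n_f = if (is.null(n_f)) NULL else as.integer(n_f),
         C_range = C_range, gamma_range = gamma_range,
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Construct a chromosome
#'
#' @param bits_C,bits_gamma,bits_mask integer 0/1 vectors for the three
#'   regions.
#' @param fitness validation accuracy in `[0, 1]`, or `NA` when unset.
#' @return a `chromosome` object.
#' @export
chromosome <- function(bits_C, bits_gamma, bits_mask, fitness = NA_real_) {
  stopifnot(all(bits_C %in% 0:1), all(bits_gamma %in% 0:1),
            all(bits_mask %in% 0:1))
  structure(
    list(bits_C = as.integer(bits_C), bits_gamma = as.integer(bits_gamma),
         bits_mask = as.integer(bits_mask), fitness = fitness),
    class = "chromosome"
  )
}

random_chromosome <- function(cfg, n_f) {
  chromosome(
    stats::rbinom(cfg$n_C, 1, 0.5),
    stats::rbinom(cfg$n_gamma, 1, 0.5),
    stats::rbinom(n_f, 1, 0.5)
  )
}

#' Decode a bit string to a real parameter value
#'
#' `P = Pmin + (Pmax - Pmin) / (2^l - 1) * d`, with `l` the bit length and
#' `d` the unsigned (most-significant-bit-first) integer value; endpoints
#' are hit exactly by the all-zero and all-one strings.
#'
#' @param bits integer 0/1 vector, MSB first.
#' @param Pmin,Pmax decoding range.
#' @return value in `[Pmin, Pmax]`.
#' @export
decode_gene <- function(bits, Pmin, Pmax) {
  l <- length(bits)
  if (l == 0) stop("empty bit string")
  stopifnot(Pmax > Pmin)
  d <- sum(bits * 2^((l - 1):0))
  Pmin + (Pmax - Pmin) / (2^l - 1) * d
}

#' Decode a chromosome to SVM parameters
#'
#' @param ch a [chromosome()].
#' @param cfg a [ga_config()].
#' @return list of class `svm_params`: `C`, `gamma`, `mask` (logical).
#' @export
decode_chromosome <- function(ch, cfg) {
  if (length(ch$bits_C) != cfg$n_C || length(ch$bits_gamma) != cfg$n_gamma) {
    stop("chromosome/config length mismatch")
  }
  structure(
    list(C = decode_gene(ch$bits_C, cfg$C_range[1], cfg$C_range[2]),
         gamma = decode_gene(ch$bits_gamma, cfg$gamma_range[1],
                             cfg$gamma_range[2]),
         mask = ch$bits_mask == 1L),
    class = "svm_params"
  )
}

#' Roulette-wheel selection
#'
#' Returns one population member with probability proportional to fitness;
#' an all-zero-fitness population falls back to uniform selection.
#'
#' @param population list of [chromosome()] objects with fitness set.
#' @return a chromosome.
#' @export
roulette_select <- function(population) {
  fit <- vapply(population, `[[`, 0, "fitness")
  stopifnot(!anyNA(fit), all(fit >= 0))
  if (sum(fit) == 0) fit <- rep(1, length(fit))
  population[[sample.int(length(population), 1, prob = fit)]]
}

# Single-point crossover of two bit vectors: a 0-based cut x is drawn
# uniformly from 0..l-1 and alleles from position x (0-based) to the end
# are exchanged; x = 0 swaps the whole region.
cross_region <- function(a, b) {
  l <- length(a)
  if (l == 0) return(list(a = a, b = b))
  x <- sample.int(l, 1) - 1L
  sel <- (x + 1L):l
  tmp <- a[sel]; a[sel] <- b[sel]; b[sel] <- tmp
  list(a = a, b = b)
}

#' Single-point crossover, per region
#'
#' With probability `p_c` the parameter region `g1|g2` and the mask region
#' `g3` each undergo independent single-point crossover (alleles from the
#' cut to the end exchanged); otherwise the parents are copied unchanged.
#'
#' @param parent1,parent2 [chromosome()] objects of matching lengths.
#' @param p_c crossover probability.
#' @return list of two child chromosomes (fitness unset).
#' @export
crossover <- function(parent1, parent2, p_c) {
  stopifnot(length(parent1$bits_C) == length(parent2$bits_C),
            length(parent1$bits_gamma) == length(parent2$bits_gamma),
            length(parent1$bits_mask) == length(parent2$bits_mask))
  if (stats::runif(1) >= p_c) {
    return(list(chromosome(parent1$bits_C, parent1$bits_gamma, parent1$bits_mask),
                chromosome(parent2$bits_C, parent2$bits_gamma, parent2$bits_mask)))
  }
  nC <- length(parent1$bits_C)
  par_ <- cross_region(c(parent1$bits_C, parent1$bits_gamma),
                       c(parent2$bits_C, parent2$bits_gamma))
  msk <- cross_region(parent1$bits_mask, parent2$bits_mask)
  list(
    chromosome(par_$a[seq_len(nC)], par_$a[-seq_len(nC)], msk$a),
    chromosome(par_$b[seq_len(nC)], par_$b[-seq_len(nC)], msk$b)
  )
}

#' Bit-flip mutation
#'
#' @param ch a [chromosome()].
#' @param p_m per-bit flip probability.
#' @return mutated chromosome (fitness unset).
#' @export
mutate <- function(ch, p_m) {
  flip <- function(bits) {
    hit <- stats::runif(length(bits)) < p_m
    as.integer(xor(bits == 1L, hit))
  }
  chromosome(flip(ch$bits_C), flip(ch$bits_gamma), flip(ch$bits_mask))
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  list(mean = mu, sd = sd_)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mean, `-`), 2, st$sd, `/`)
}

fit_rbf_svm <- function(X, y, C, gamma) {
  e1071::svm(x = X, y = factor(y), type = "C-classification",
             kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
}

#' Fitness of a chromosome
#'
#' Decodes the chromosome, standardizes the features with training-set
#' statistics, trains an RBF-kernel soft-margin SVM with the decoded
#' `(C, gamma)` on the masked features and returns the validation accuracy.
#' An all-zero mask is untrainable and scores 0; a solver failure scores 0
#' with a warning.
#'
#' @param ch a [chromosome()].
#' @param train_X,validation_X numeric feature matrices with `n_f` columns.
#' @param train_y,validation_y label vectors.
#' @param cfg a [ga_config()].
#' @return accuracy in `[0, 1]`.
#' @export
ga_fitness <- function(ch, train_X, train_y, validation_X, validation_y, cfg) {
  params <- decode_chromosome(ch, cfg)
  if (!any(params$mask)) return(0)
  st <- standardize_fit(train_X)
  trX <- standardize_apply(train_X, st)[, params$mask, drop = FALSE]
  vaX <- standardize_apply(validation_X, st)[, params$mask, drop = FALSE]
  tryCatch({
    fit <- fit_rbf_svm(trX, train_y, params$C, params$gamma)
    mean(as.character(stats::predict(fit, vaX)) == as.character(validation_y))
  }, error = function(e) {
    warning("SVM solver failure, fitness set to 0: ", conditionMessage(e))
    0
  })
}

#' Run the genetic algorithm
#'
#' Initializes a random population, then per generation: evaluates fitness,
#' copies the top `ceiling(elitism_rate * population_size)` chromosomes
#' unchanged, and fills the remainder by roulette selection, per-region
#' single-point crossover and bit-flip mutation. Returns the best-ever
#' chromosome (whose fitness is non-decreasing across generations under
#' elitism).
#'
#' @param train_X,train_y,validation_X,validation_y feature matrices and
#'   labels for the binary stage being optimized.
#' @param cfg a [ga_config()]; `cfg$n_f` defaults to `ncol(train_X)`.
#' @return list of class `ga_result`: `best` (chromosome), `params`
#'   (decoded [decode_chromosome()]), and `history` (data frame with
#'   per-generation best and mean fitness; generation 0 is the initial
#'   population).
#' @export
run_ga <- function(train_X, train_y, validation_X, validation_y, cfg) {
  stopifnot(inherits(cfg, "ga_config"))
  n_f <- if (is.null(cfg$n_f)) ncol(train_X) else cfg$n_f
  stopifnot(n_f == ncol(train_X), ncol(validation_X) == ncol(train_X))
  with_seed(cfg$seed, {
    evaluate <- function(pop) {
      lapply(pop, function(ch) {
        if (is.na(ch$fitness)) {
          ch$fitness <- ga_fitness(ch, train_X, train_y, validation_X,
                                   validation_y, cfg)
        }
        ch
      })
    }
    pop <- evaluate(lapply(seq_len(cfg$population_size), function(i) {
      random_chromosome(cfg, n_f)
    }))
    n_elite <- ceiling(cfg$elitism_rate * cfg$population_size)
    hist_rows <- list()
    record <- function(gen, pop) {
      fit <- vapply(pop, `[[`, 0, "fitness")
      data.frame(generation = gen, best = max(fit), mean = mean(fit))
    }
    hist_rows[[1]] <- record(0, pop)
    best_ever <- pop[[which.max(vapply(pop, `[[`, 0, "fitness"))]]
    for (gen in seq_len(cfg$generations)) {
      fit <- vapply(pop, `[[`, 0, "fitness")
      elite <- pop[order(fit, decreasing = TRUE)[seq_len(n_elite)]]
      nxt <- elite
      while (length(nxt) < cfg$population_size) {
        p1 <- roulette_select(pop)
        p2 <- roulette_select(pop)
        kids <- crossover(p1, p2, cfg$p_crossover)
        kids <- lapply(kids, mutate, p_m = cfg$p_mutation)
        nxt <- c(nxt, kids)
      }
      pop <- evaluate(nxt[seq_len(cfg$population_size)])
      fit <- vapply(pop, `[[`, 0, "fitness")
      if (max(fit) > best_ever$fitness) pop[[which.max(fit)]] -> best_ever
      hist_rows[[gen + 1]] <- record(gen, pop)
    }
    structure(
      list(best = best_ever, params = decode_chromosome(best_ever, cfg),
           history = do.call(rbind, hist_rows)),
      class = "ga_result"
    )
  })
}

feature_matrix <- function(features) {
  as.matrix(features[, grep("^f[0-9]{2}_", names(features)), drop = FALSE])
}

train_stage <- function(train_X, train_y, validation_X, validation_y, cfg) {
  ga <- run_ga(train_X, train_y, validation_X, validation_y, cfg)
  st <- standardize_fit(train_X)
  fit <- fit_rbf_svm(
    standardize_apply(train_X, st)[, ga$params$mask, drop = FALSE],
    train_y, ga$params$C, ga$params$gamma
  )
  list(model = fit, params = ga$params, scaler = st, ga = ga)
}

#' Train the two-stage SVM cascade
#'
#' Stage 1 separates normal lymphocytes from blasts (pre-T and pre-B
#' pooled); stage 2 separates pre-T from pre-B and is trained on blast
#' samples only. Each stage gets its own GA run (feature mask and
#' hyperparameters) with a seed derived from `cfg$seed`.
#'
#' @param train_features,validation_features feature tables from
#'   [extract_features()] (columns `label` and `f01_...`-`f46_...`).
#' @param cfg a [ga_config()].
#' @return a `cascade_model` with elements `stage1`, `stage2` (fitted SVM +
#'   decoded params + scaler + GA history).
#' @export
train_cascade <- function(train_features, validation_features, cfg) {
  trX <- feature_matrix(train_features)
  vaX <- feature_matrix(validation_features)
  tr_lab <- train_features$label
  va_lab <- validation_features$label
  if (!all(BLAST_CLASSES %in% tr_lab)) stop("a class is absent from training data")
  cfg1 <- cfg; cfg1$seed <- derive_seed(cfg$seed, 1L)
  s1 <- train_stage(trX, ifelse(tr_lab == "lymphocyte", "normal", "blast"),
                    vaX, ifelse(va_lab == "lymphocyte", "normal", "blast"),
                    cfg1)
  tr_bl <- tr_lab != "lymphocyte"
  va_bl <- va_lab != "lymphocyte"
  cfg2 <- cfg; cfg2$seed <- derive_seed(cfg$seed, 2L)
  s2 <- train_stage(trX[tr_bl, , drop = FALSE], tr_lab[tr_bl],
                    vaX[va_bl, , drop = FALSE], va_lab[va_bl], cfg2)
  structure(list(stage1 = s1, stage2 = s2), class = "cascade_model")
}

stage_predict <- function(stage, X) {
  Xs <- standardize_apply(X, stage$scaler)[, stage$params$mask, drop = FALSE]
  as.character(stats::predict(stage$model, Xs))
}

#' Predict with the two-stage cascade
#'
#' Samples called normal by stage 1 are labelled `lymphocyte` and never
#' reach stage 2; the rest are labelled `pre_T` or `pre_B` by stage 2.
#'
#' @param model a `cascade_model` from [train_cascade()].
#' @param features feature table or plain numeric matrix with the full
#'   feature-column layout (per-stage masking is applied internally).
#' @return character vector of predicted class labels.
#' @export
predict_cascade <- function(model, features) {
  X <- if (is.data.frame(features)) feature_matrix(features) else features
  if (ncol(X) != length(model$stage1$params$mask)) {
    stop("feature column-count mismatch")
  }
  out <- rep("lymphocyte", nrow(X))
  p1 <- stage_predict(model$stage1, X)
  blast <- p1 == "blast"
  if (any(blast)) {
    out[blast] <- stage_predict(model$stage2, X[blast, , drop = FALSE])
  }
  out
}
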