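# Gaussian-cluster feature fixture: `informative` columns carry class
# signal, the rest are noise.
cluster_features <- function(n_per_class, n_features = 20, informative = 1:5,
                             sep = 3, seed = 1, classes = c("a", "b")) {
  blastclass:::with_seed(seed, {
    X <- matrix(rnorm(sum(n_per_class) * n_features), ncol = n_features)
    y <- rep(classes, n_per_class)
    for (k in seq_along(classes)) {
      rows <- y == classes[k]
      X[rows, informative] <- X[rows, informative] + (k - 1) * sep
    }
    list(X = X, y = y)
  })
}

test_that("gene decoding is endpoint-exact, matches hand evaluation, monotone", {
  expect_equal(decode_gene(rep(0L, 20), 0.01, 10000), 0.01)
  expect_equal(decode_gene(rep(1L, 20), 0.01, 10000), 10000)
  # two-bit string "01" over [0, 3]: d = 1, step = 3/3 -> 1.0
  expect_equal(decode_gene(c(0L, 1L), 0, 3), 1.0)
  expect_error(decode_gene(integer(0), 0, 1), "empty")
  vals <- sapply(0:7, function(d) {
    decode_gene(as.integer(intToBits(d))[3:1], -1, 5)
  })
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[1], -1)
  expect_equal(vals[8], 5)
})

test_that("chromosome decoding maps regions to C, gamma and mask", {
  cfg <- ga_config(n_C = 4, n_gamma = 4, n_f = 6, C_range = c(1, 17),
                   gamma_range = c(0.5, 2))
  ch <- chromosome(rep(1L, 4), rep(1L, 4), c(1L, 0L, 1L, 1L, 0L, 0L))
  p <- decode_chromosome(ch, cfg)
  expect_equal(p$C, 17)
  expect_equal(p$gamma, 2)
  expect_identical(p$mask, c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(p, decode_chromosome(ch, cfg))  # pure function
  expect_error(decode_chromosome(chromosome(1L, rep(1L, 4), rep(0L, 6)), cfg),
               "length mismatch")
})

test_that("roulette selection is fitness-proportional", {
  mkpop <- function(fit) {
    lapply(seq_along(fit), function(i) {
      # encode the member index in the C bits so draws are identifiable
      chromosome(as.integer(intToBits(i))[1:4], 1L, 1L, fitness = fit[i])
    })
  }
  member <- function(ch) sum(ch$bits_C * 2^(0:3))
  draws <- function(fit, n = 10000, seed = 42) {
    pop <- mkpop(fit)
    blastclass:::with_seed(seed, replicate(n, member(roulette_select(pop))))
  }
  d <- draws(c(3, 1))
  expect_lt(abs(mean(d == 1) - 0.75), 0.03)
  d2 <- draws(c(1, 1, 1, 1), seed = 43)
  freq <- tabulate(d2, 4) / length(d2)
  expect_true(all(abs(freq - 0.25) < 0.02))
  # degenerate wheel: only the positive-fitness member can be drawn
  d3 <- draws(c(1, 0, 0), n = 200, seed = 7)
  expect_true(all(d3 == 1))
})

test_that("crossover exchanges tails per region; mutation flips at rate p_m", {
  p1 <- chromosome(rep(0L, 4), rep(0L, 4), rep(0L, 4))
  p2 <- chromosome(rep(1L, 4), rep(1L, 4), rep(1L, 4))
  same <- blastclass:::with_seed(1, crossover(p1, p2, p_c = 0))
  expect_identical(same[[1]]$bits_mask, p1$bits_mask)
  expect_identical(same[[2]]$bits_C, p2$bits_C)
  # with p_c = 1 every child region is a 0-1 or 1-0 tail-swap pattern;
  # brute-force enumeration of all cut points x = 0..l-1
  tail_patterns <- function(l) {
    unique(do.call(rbind, lapply(0:(l - 1), function(x) {
      rbind(c(rep(0, x), rep(1, l - x)), c(rep(1, x), rep(0, l - x)))
    })))
  }
  pat8 <- tail_patterns(8)   # parameter region g1|g2 (4 + 4 bits)
  pat4 <- tail_patterns(4)   # mask region g3
  in_set <- function(bits, pats) any(apply(pats, 1, identical, y = as.numeric(bits)))
  blastclass:::with_seed(11, {
    for (i in 1:25) {
      kids <- crossover(p1, p2, p_c = 1)
      for (k in kids) {
        expect_true(in_set(c(k$bits_C, k$bits_gamma), pat8))
        expect_true(in_set(k$bits_mask, pat4))
      }
      # children are complementary region-wise
      expect_equal(c(kids[[1]]$bits_mask + kids[[2]]$bits_mask), rep(1, 4))
    }
  })

  expect_identical(blastclass:::with_seed(2, mutate(p1, 0))$bits_mask, p1$bits_mask)
  expect_identical(blastclass:::with_seed(2, mutate(p1, 1))$bits_mask, rep(1L, 4))
  big <- chromosome(rep(0L, 5000), rep(0L, 2500), rep(0L, 2500))
  mut <- blastclass:::with_seed(3, mutate(big, 0.06))
  frac <- mean(c(mut$bits_C, mut$bits_gamma, mut$bits_mask))
  expect_lt(abs(frac - 0.06), 0.01)
})

test_that("fitness: separable task scores 1, zero mask scores 0, deterministic", {
  tr <- cluster_features(c(20, 20), sep = 6, seed = 5)
  va <- cluster_features(c(15, 15), sep = 6, seed = 6)
  cfg <- ga_config(n_C = 8, n_gamma = 8, n_f = 20, seed = 1)
  ch <- chromosome(rep(0L, 8), rep(0L, 8), rep(1L, 20))
  ch$bits_C[5] <- 1L  # moderate C
  f1 <- ga_fitness(ch, tr$X, tr$y, va$X, va$y, cfg)
  expect_equal(f1, 1.0)
  expect_equal(ga_fitness(ch, tr$X, tr$y, va$X, va$y, cfg), f1)
  zero <- chromosome(rep(1L, 8), rep(0L, 8), rep(0L, 20))
  expect_equal(ga_fitness(zero, tr$X, tr$y, va$X, va$y, cfg), 0)
})

test_that("GA: boundary generations, elitism monotonicity, constant population", {
  tr <- cluster_features(c(15, 15), sep = 2, seed = 2)
  va <- cluster_features(c(12, 12), sep = 2, seed = 3)
  cfg0 <- ga_config(population_size = 6, generations = 0, n_C = 6, n_gamma = 6,
                    seed = 4)
  r0 <- run_ga(tr$X, tr$y, va$X, va$y, cfg0)
  expect_equal(nrow(r0$history), 1)
  expect_equal(r0$best$fitness, r0$history$best[1])

  for (sd in 1:3) {
    cfg <- ga_config(population_size = 8, generations = 5, n_C = 6,
                     n_gamma = 6, seed = sd)
    r <- run_ga(tr$X, tr$y, va$X, va$y, cfg)
    expect_true(all(diff(cummax(r$history$best)) >= 0))
    # elitism: per-generation best never drops
    expect_true(all(diff(r$history$best) >= -1e-12))
    expect_equal(nrow(r$history), 6)
    expect_gte(r$best$fitness, max(r$history$best) - 1e-12)
  }
})

test_that("GA-selected masks beat random masks of equal size on clusters", {
  wins <- 0
  diffs <- numeric(5)
  for (sd in 1:5) {
    tr <- cluster_features(c(25, 25), n_features = 20, informative = 1:5,
                           sep = 1.5, seed = 10 + sd)
    va <- cluster_features(c(20, 20), n_features = 20, informative = 1:5,
                           sep = 1.5, seed = 30 + sd)
    cfg <- ga_config(population_size = 14, generations = 8, n_C = 8,
                     n_gamma = 8, seed = sd)
    r <- run_ga(tr$X, tr$y, va$X, va$y, cfg)
    ga_acc <- r$best$fitness
    # random mask of the same cardinality, same decoded hyperparameters
    rand_acc <- blastclass:::with_seed(100 + sd, {
      mean(replicate(10, {
        mask_bits <- integer(20)
        mask_bits[sample(20, sum(r$params$mask))] <- 1L
        ch <- chromosome(r$best$bits_C, r$best$bits_gamma, mask_bits)
        ga_fitness(ch, tr$X, tr$y, va$X, va$y, cfg)
      }))
    })
    diffs[sd] <- ga_acc - rand_acc
  }
  expect_gt(mean(diffs), 0)
})

test_that("cascade recovers well-separated three-class structure and routes stages", {
  fnames <- feature_names(prefixed = TRUE)
  mk_table <- function(n, seed) {
    blastclass:::with_seed(seed, {
      lab <- rep(blast_classes(), each = n)
      X <- matrix(rnorm(length(lab) * 46), ncol = 46)
      X[lab == "pre_T", 1:6] <- X[lab == "pre_T", 1:6] + 4
      X[lab == "pre_B", 7:12] <- X[lab == "pre_B", 7:12] + 4
      df <- as.data.frame(X)
      names(df) <- fnames
      cbind(data.frame(source_id = paste0("s", seq_along(lab)), label = lab),
            df)
    })
  }
  accs <- sapply(1:3, function(sd) {
    tr <- mk_table(12, seed = sd)
    va <- mk_table(8, seed = 50 + sd)
    te <- mk_table(10, seed = 80 + sd)
    # gamma range sized to standardized 46-dim inputs (useful widths are
    # well below 1); the decoding range is a per-task configuration knob
    cfg <- ga_config(population_size = 10, generations = 4, n_C = 8,
                     n_gamma = 8, gamma_range = c(1e-4, 0.5), seed = sd)
    model <- train_cascade(tr, va, cfg)
    # stage 2 never sees normal lymphocytes
    expect_identical(sort(as.character(model$stage2$model$levels)),
                     c("pre_B", "pre_T"))
    pred <- predict_cascade(model, te)
    # stage-1 "normal" decisions map to lymphocyte and bypass stage 2
    p1 <- blastclass:::stage_predict(model$stage1, blastclass:::feature_matrix(te))
    expect_identical(pred == "lymphocyte", p1 == "normal")
    mean(pred == te$label)
  })
  expect_true(all(accs > 0.9))

  tr <- mk_table(6, seed = 1)
  no_lymph <- tr[tr$label != "lymphocyte", ]
  cfg <- ga_config(population_size = 6, generations = 1, n_C = 4, n_gamma = 4,
                   seed = 1)
  expect_error(train_cascade(no_lymph, no_lymph, cfg), "absent")
  model <- train_cascade(tr, tr, cfg)
  expect_error(predict_cascade(model, matrix(0, 2, 10)), "mismatch")
})
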