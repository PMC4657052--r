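test_that("distance features follow the nearest-residue definition", {
  f <- distance_features("AKMRA", 3)
  expect_equal(unname(f["NT_K"]), 1)
  expect_equal(unname(f["NT_A"]), 2)
  expect_equal(unname(f["CT_R"]), 1)
  expect_equal(unname(f["CT_A"]), 2)
  # absent in a direction: protein length default
  expect_equal(unname(f["NT_R"]), 5)
  expect_equal(unname(f["CT_K"]), 5)
  expect_equal(unname(f["NT_W"]), 5)

  f2 <- distance_features("MMM", 2)
  expect_equal(unname(f2["NT_M"]), 1)
  expect_equal(unname(f2["CT_M"]), 1)

  expect_error(distance_features("AKMRA", 2), "not M")
  expect_error(distance_features("AKMRA", 9), "out of range")
})

test_that("distance features agree with a brute-force scan", {
  brute <- function(seq, pos) {
    ch <- strsplit(seq, "")[[1]]
    L <- length(ch)
    out <- numeric(0)
    for (aa in metox:::AA20) {
      nt <- L; ct <- L
      for (i in seq_len(L)) {
        if (i < pos && ch[i] == aa) nt <- pos - i
        if (i > pos && ch[i] == aa && ct == L) ct <- i - pos
      }
      out <- c(out, setNames(c(nt, ct), paste0(c("NT_", "CT_"), aa)))
    }
    out[c(paste0("NT_", metox:::AA20), paste0("CT_", metox:::AA20))]
  }
  set.seed(101)
  for (rep in seq_len(1000)) {
    L <- sample(12:60, 1)
    ch <- sample(metox:::AA20, L, replace = TRUE)
    pos <- sample(L, 1)
    ch[pos] <- "M"
    seq <- paste(ch, collapse = "")
    expect_identical(distance_features(seq, pos), brute(seq, pos))
  }
})

test_that("benchmark assembly labels, defaults and deduplicates", {
  prot <- data.frame(
    id = c("P1", "P2"),
    seq = c("AKMRAKYMCD", "MAAAAMAAAA"),  # P2 lacks W entirely
    stringsAsFactors = FALSE)
  sites <- data.frame(
    protein_id = c("P1", "P1", "P2", "P2", "P2"),
    pos = c(3, 8, 6, 6, 1),
    oxidized = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  tab <- assemble_benchmark(sites, prot)
  expect_equal(nrow(tab), 4)  # duplicate (P2, 6) collapsed
  expect_equal(unname(attr(tab, "class_counts")),
               c(3L, 1L), ignore_attr = TRUE)
  no_w <- tab[tab$protein_id == "P2" & tab$pos == 6, ]
  expect_equal(no_w$NT_W, 10)
  expect_equal(no_w$CT_W, 10)
  expect_equal(levels(tab$label), c("oxidized", "resistant"))
})

test_that("random forest learns a separable rule and is reproducible", {
  cfg <- synthetic_config(n_proteins = 60, mean_length = 200)
  pl <- plant_env_bias(gen_proteome(cfg, 21), cfg, 22)
  tab <- assemble_benchmark(pl$sites, pl$proteome)
  tab$label <- factor(ifelse(tab$NT_Y <= 3, "oxidized", "resistant"),
                      levels = c("oxidized", "resistant"))
  rep1 <- train_rf(tab, seed = 5, ntree = 200, folds = 3, repeats = 1)
  expect_gte(rep1$test$accuracy, 0.95)
  expect_gte(rep1$cv$auc, 0.95)
  expect_equal(rep1$n_train + rep1$n_test, nrow(tab))

  rep2 <- train_rf(tab, seed = 5, ntree = 200, folds = 3, repeats = 1)
  expect_identical(rep1$cv, rep2$cv)
  expect_identical(rep1$test, rep2$test)

  single <- tab
  single$label <- factor(rep("oxidized", nrow(tab)),
                         levels = c("oxidized", "resistant"))
  expect_error(train_rf(single, seed = 1), "both classes")
})

test_that("random labels give chance-level test AUC on average", {
  set.seed(606)
  n <- 200
  tab <- as.data.frame(matrix(sample(1:60, n * 40, TRUE), n, 40))
  names(tab) <- c(paste0("NT_", metox:::AA20), paste0("CT_", metox:::AA20))
  aucs <- vapply(1:10, function(sd) {
    tab$label <- factor(sample(c("oxidized", "resistant"), n, TRUE),
                        levels = c("oxidized", "resistant"))
    train_rf(tab, seed = sd, ntree = 100, folds = 2,
             repeats = 1)$test$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("recursive feature elimination recovers planted features", {
  set.seed(99)
  n <- 240
  tab <- as.data.frame(matrix(sample(1:50, n * 40, TRUE), n, 40))
  names(tab) <- c(paste0("NT_", metox:::AA20), paste0("CT_", metox:::AA20))
  tab$label <- factor(ifelse(tab$NT_M + tab$CT_M < 50,
                             "oxidized", "resistant"),
                      levels = c("oxidized", "resistant"))
  r <- rfe_select(tab, seed = 3, sizes = c(2, 4, 8, 16, 32), folds = 3,
                  ntree = 150)
  expect_true(all(c("NT_M", "CT_M") %in% r$selected))
  # curve covers the requested sizes plus the full set
  expect_equal(r$curve$size, c(2, 4, 8, 16, 32, 40))
  expect_equal(length(r$selected), r$best_size)
})
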