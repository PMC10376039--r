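test_that("schema validation enforces names, kinds and levels", {
  expect_error(covariate_schema(c("a", "a"), c("binary", "binary")),
               "unique")
  expect_error(covariate_schema("", "binary"), "non-empty")
  expect_error(covariate_schema("f", "categorical"), "at least 2")
  sch <- covariate_schema(c("f", "b"), c("categorical", "binary"),
                          list(f = c("lo", "hi")))
  expect_s3_class(sch, "covariate_schema")
  expect_equal(sch$levels$b, c(0, 1))
})

test_that("dataset construction validates rows against the schema", {
  sch <- tooth_schema()
  expect_error(es_dataset(data.frame(dose = 3.0, supp = 0), 5, sch),
               "outside declared levels at row 1")
  expect_error(es_dataset(data.frame(dose = c(0.5, 1)), c(1, 2), sch),
               "missing covariate")
  expect_error(es_dataset(data.frame(dose = 0.5, supp = 0), c(1, 2), sch),
               "differ")
  d <- es_dataset(data.frame(dose = c(0.5, 2), supp = c(0, 1)), c(4, 30),
                  sch)
  expect_equal(d$n, 2)
  expect_equal(d$m, 2)
})

test_that("the bundled tooth-growth table loads with n = 60 and supp 0/1", {
  d <- tooth_growth()
  expect_equal(d$n, 60)
  expect_equal(d$m, 2)
  expect_setequal(unique(d$covariates$supp), c(0, 1))
  expect_equal(sum(d$covariates$dose == 0.5), 20)
})

test_that("CSV round trip preserves the dataset exactly", {
  d <- tooth_growth()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  save_csv(d, path, response_column = "len")
  d2 <- load_csv(path, tooth_schema(), "len")
  expect_identical(d2$covariates, d$covariates)
  expect_identical(d2$response, d$response)

  # header-only file -> empty dataset is allowed
  writeLines("len,supp,dose", path)
  d0 <- load_csv(path, tooth_schema(), "len")
  expect_equal(d0$n, 0)

  # VC/OJ text labels recode to 0/1
  writeLines(c("len,supp,dose", "10,VC,0.5", "20,OJ,1"), path)
  dv <- load_csv(path, tooth_schema(), "len")
  expect_equal(dv$covariates$supp, c(0, 1))

  # out-of-schema dose value is rejected with the row index
  writeLines(c("len,supp,dose", "10,VC,3.0"), path)
  expect_error(load_csv(path, tooth_schema(), "len"), "row 1")
  expect_error(load_csv(path, tooth_schema(), "nope"), "nope")
})

test_that("one-hot encoding expands levels in schema order and is exact", {
  d <- tooth_growth()
  e <- encode_m2(d)
  expect_equal(e$m, 4)
  expect_equal(e$schema$names, c("dose_0.5", "dose_1", "dose_2", "supp"))
  expect_true(all(e$schema$kinds == "binary"))
  # a dose 1.0 row maps to the indicator triple (0, 1, 0)
  i <- which(d$covariates$dose == 1.0)[1]
  expect_equal(unlist(e$covariates[i, 1:3], use.names = FALSE), c(0, 1, 0))
  # each original covariate's indicator block sums to one in every row
  expect_true(all(rowSums(e$covariates[, 1:3]) == 1))
  # already-binary data passes through unchanged
  expect_identical(encode_m2(e), e)
})

test_that("train/test splits have the right size and are deterministic", {
  sp <- split_train_test(60, 0.7, 11)
  expect_length(sp$train, 42)
  expect_length(sp$test, 18)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:60)
  expect_identical(split_train_test(10, 0.7, 3), split_train_test(10, 0.7, 3))
  expect_error(split_train_test(2, 0.9, 1), "empty")
  expect_error(split_train_test(1, 0.5, 1), "n >= 2")
  expect_error(split_train_test(10, 1.5, 1), "between 0 and 1")
})

test_that("split membership frequency is ~ the training fraction", {
  counts <- integer(60)
  for (s in 1:1000) {
    sp <- split_train_test(60, 0.7, s)
    counts[sp$train] <- counts[sp$train] + 1L
  }
  expect_true(all(abs(counts / 1000 - 0.7) <= 0.05))
})

test_that("cell means average the response per covariate level", {
  d <- toy_tooth(reps = 2, sigma = 0)
  cm <- cell_means(d)
  expect_named(cm, c("dose", "supp"))
  expect_equal(unname(cm$dose["0.5"]), mean(c(8, 13)))
  expect_equal(unname(cm$supp["1"]), mean(c(13, 22, 26)))
  # constant response: every cell mean is that constant
  dc <- es_dataset(d$covariates, rep(7, d$n), d$schema)
  expect_true(all(unlist(cell_means(dc)) == 7))
  # single-element cells
  d2 <- es_dataset(data.frame(x = c(0.5, 1.0)), c(10, 20),
                   covariate_schema("x", "ordinal", list(x = c(0.5, 1.0))))
  expect_equal(unname(cell_means(d2)$x), c(10, 20))
  # a missing level is an error naming covariate and level
  d3 <- subset_rows(tooth_growth(), which(tooth_growth()$covariates$dose != 2))
  expect_error(cell_means(d3), "level '2' of covariate 'dose'")
})
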