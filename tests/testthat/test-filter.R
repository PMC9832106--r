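make_outputs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(pre_MAP = r[1], pre_CO = r[2], pre_P_pv = r[3],
               pre_PCG = r[4])))
}

test_that("the acceptance box retains physiological rows, closed at the bounds", {
  out <- make_outputs(c(90, 5, 10, 5),    # inside
                      c(140, 5, 10, 5),   # MAP above max
                      c(130, 5, 10, 5),   # exactly on the MAP bound
                      c(90, 2.9, 10, 5),  # CO below
                      c(90, 5, 10, 14),   # PCG on the bound
                      c(90, 5, 20.1, 5))  # P_pv above
  expect_identical(apply_filter(out),
                   c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_error(apply_filter(out[, -1]), "missing output column")
  expect_error(filter_bounds(MAP = c(130, 50)), "min < max")
})

test_that("filtering is idempotent and monotone in the bounds", {
  set.seed(12)
  out <- data.frame(pre_MAP = runif(300, 40, 150),
                    pre_CO = runif(300, 2, 11),
                    pre_P_pv = runif(300, 2, 25),
                    pre_PCG = runif(300, 0, 16))
  b <- filter_bounds()
  m1 <- apply_filter(out, b)
  # idempotence: filtering the filtered set changes nothing
  expect_true(all(apply_filter(out[m1, ], b)))
  # tightening any bound never increases the retained set
  tight <- filter_bounds(MAP = c(60, 120))
  m2 <- apply_filter(out, tight)
  expect_true(all(which(m2) %in% which(m1)))
  expect_lte(sum(m2), sum(m1)) # N* <= N
})

test_that("population assembly keeps provenance and round-trips through CSV", {
  set.seed(13)
  coh <- generate_synthetic_cohort(default_cohort_spec(), n = 40, seed = 2)
  out <- data.frame(pre_MAP = runif(40, 70, 110), pre_CO = runif(40, 4, 6),
                    pre_P_pv = runif(40, 6, 14), pre_PCG = runif(40, 3, 9),
                    post_P_pv = runif(40, 8, 18))
  mask <- apply_filter(out)
  pop <- assemble_population(coh, out, mask, seed = 2)
  expect_equal(attr(pop, "n_total"), 40)
  expect_equal(attr(pop, "n_retained"), sum(mask))
  expect_true(attr(pop, "n_retained") <= attr(pop, "n_total"))
  expect_false(is.null(attr(pop, "provenance")$bounds))
  # all-true and empty masks
  all_pop <- assemble_population(coh, out, rep(TRUE, 40))
  expect_equal(attr(all_pop, "n_retained") / attr(all_pop, "n_total"), 1)
  none <- assemble_population(coh, out, rep(FALSE, 40))
  expect_equal(nrow(none), 0)
  expect_identical(names(none), c(names(coh), names(out)))
  expect_error(assemble_population(coh[1:10, ], out, mask), "misaligned")
  # round trip
  f <- file.path(tempdir(), "pop.csv")
  write_population(pop, f)
  back <- read_population(f)
  expect_equal(as.data.frame(pop), as.data.frame(back), tolerance = 1e-12)
  expect_equal(attr(back, "n_retained"), attr(pop, "n_retained"))
})

test_that("median comparison reports all outputs and phases", {
  df <- as.data.frame(matrix(rnorm(50 * 12, 10), 50))
  names(df) <- c(paste0("pre_", output_names()),
                 paste0("post_", output_names()))
  r <- compare_distributions(df, df)
  expect_equal(nrow(r), 12)
  expect_true(all(r$abs_diff == 0))
  # medians 10.0 vs 9.6 -> 0.4 mmHg and ~4.17%
  a <- df; a$pre_P_pv <- a$pre_P_pv - median(a$pre_P_pv) + 10
  b <- df; b$pre_P_pv <- b$pre_P_pv - median(b$pre_P_pv) + 9.6
  row <- compare_distributions(a, b)
  i <- which(row$output == "P_pv" & row$phase == "pre-hpx")
  expect_equal(row$abs_diff[i], 0.4, tolerance = 1e-9)
  expect_equal(row$pct_diff[i], 100 * 0.4 / 9.6, tolerance = 1e-9)
  expect_error(compare_distributions(df[, -1], df), "missing")
})

test_that("the retained-region summary bounds the population it came from", {
  coh <- generate_synthetic_cohort(default_cohort_spec(), n = 300, seed = 5)
  out <- data.frame(pre_MAP = runif(300, 70, 110),
                    pre_CO = runif(300, 4, 6),
                    pre_P_pv = runif(300, 6, 14),
                    pre_PCG = runif(300, 3, 9))
  pop <- assemble_population(coh, out, rep(TRUE, 300))
  reg <- filtered_input_summary(pop)
  # unfiltered population: retained ranges equal cohort ranges
  for (nm in input_names())
    expect_equal(as.numeric(reg$ranges[, nm]), range(coh[[nm]]), info = nm)
  # occupancy mass sums to the retained count
  for (g in reg$grids)
    expect_equal(sum(g$counts), 300)
  # every retained point is inside the admissible region
  inside <- vapply(seq_len(nrow(coh)), function(i)
    in_admissible_region(reg, as.list(coh[i, ])), TRUE)
  expect_true(all(inside))
  # a point far outside is rejected
  far <- as.list(coh[1, ]); far$Eb_LV <- 10
  expect_false(in_admissible_region(reg, far))
  expect_error(filtered_input_summary(pop[0, ]), "empty")
})
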