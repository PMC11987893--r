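test_that("fat and weight group boundaries follow the plan encoding", {
  plan <- stratification_plan()
  expect_identical(assign_fat_group(c(9, 10, 11, 18, 18.5), plan),
                   c(1L, 1L, 2L, 2L, 3L))
  expect_identical(assign_weight_group(c(84.4, 84.5, 120, 60, 100), plan),
                   c("A", "B", "C", "A", "B"))
  # values in the printed label gaps are still classifiable
  expect_identical(assign_fat_group(10.5, plan), 2L)
  expect_identical(assign_weight_group(84.45, plan), "B")
  expect_error(assign_fat_group(0), "positive")
  expect_error(assign_weight_group(59.9, plan), "outside the plan range")
  expect_error(assign_weight_group(120.1, plan), "outside the plan range")
})

test_that("group assignment partitions the plan range and is monotone", {
  plan <- stratification_plan()
  f2 <- seq(0.5, 40, by = 0.25)
  g <- assign_fat_group(f2, plan)
  expect_true(all(g %in% 1:3))
  expect_true(!is.unsorted(g))                  # monotone in f2
  w <- seq(60, 120, by = 0.1)
  gw <- assign_weight_group(w, plan)
  expect_true(all(gw %in% c("A", "B", "C")))
  expect_true(!is.unsorted(match(gw, LETTERS)))
})

test_that("the default plan carries the published design totals", {
  plan <- stratification_plan()
  expect_equal(sum(plan$required_counts), 126)
  expect_equal(unname(colSums(plan$required_counts)), c(30, 66, 30))
  expect_equal(unname(rowSums(plan$required_counts)), c(32, 62, 32))
  expect_equal(sum(plan$required_subsample), 12)
  expect_true(validate_plan(plan)$ok)
})

test_that("plan validation flags flat ratios and thin subsamples", {
  flat <- stratification_plan(
    required_counts = matrix(10, 3, 3),
    required_subsample = matrix(1, 3, 3))
  v <- validate_plan(flat)
  expect_false(v$ratio_fat_ok)
  expect_false(v$ratio_weight_ok)
  thin <- stratification_plan(
    required_subsample = matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0), 3,
                                byrow = TRUE))
  expect_false(validate_plan(thin)$subsample_ok)  # 3 of 126 ~ 2.4%
})

test_that("selection achieves the plan exactly on an ample population", {
  pop <- generate_population(population_params(20000, seed = 21))
  sel <- select_sample(pop, seed = 31)
  expect_equal(nrow(sel$selected), 126)
  expect_equal(sum(sel$selected$in_subsample), 12)
  expect_equal(unname(sel$achieved_counts),
               unname(stratification_plan()$required_counts))
  expect_equal(nrow(sel$shortfalls), 0)
  # every selected carcass sits in its labelled cell
  expect_identical(assign_fat_group(sel$selected$f2_mm),
                   sel$selected$fat_group)
  expect_identical(assign_weight_group(sel$selected$hot_weight_kg),
                   sel$selected$weight_group)
  # without replacement
  expect_false(anyDuplicated(sel$selected$id) > 0)
  # deterministic under the seed
  sel2 <- select_sample(pop, seed = 31)
  expect_identical(sel$selected$id, sel2$selected$id)
})

test_that("an exact-fit population is selected in full without shortfall", {
  pop <- generate_population(population_params(20000, seed = 77))
  exact <- select_sample(pop, seed = 5)$selected
  exact$fat_group <- exact$weight_group <- exact$in_subsample <- NULL
  sel <- select_sample(exact, seed = 9)
  expect_equal(sort(sel$selected$id), sort(exact$id))
  expect_equal(nrow(sel$shortfalls), 0)
})

test_that("empty cells are recorded as shortfalls, not errors", {
  pop <- generate_population(population_params(20000, seed = 13))
  # remove every candidate of the (A, fat 3) cell
  drop <- assign_weight_group(pop$hot_weight_kg) == "A" &
    assign_fat_group(pop$f2_mm) == 3L
  sel <- select_sample(pop[!drop, ], seed = 4)
  expect_equal(nrow(sel$shortfalls), 1)
  expect_equal(sel$shortfalls$weight_group, "A")
  expect_equal(sel$shortfalls$fat_group, 3L)
  expect_equal(sel$shortfalls$deficit, 7)
  # cell-wise accounting: achieved + deficit == required
  deficits <- stratification_plan()$required_counts - sel$achieved_counts
  expect_equal(sum(deficits), 7)
})

test_that("duplicate ids in the population are rejected", {
  pop <- generate_population(small_params(n = 100, seed = 2))
  pop$id[2] <- pop$id[1]
  expect_error(select_sample(pop, seed = 1), "duplicate")
})
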