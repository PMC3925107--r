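test_that("shannon_entropy matches hand-summed values and conventions", {
  expect_identical(shannon_entropy(1.0), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1.0)
  # frozen from the hand-summation oracle: -(0.5*log2 0.5 + 2*0.25*log2 0.25)
  expect_equal(oracle_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  # zero-probability entries contribute nothing
  expect_equal(shannon_entropy(c(0.5, 0.5, 0)), 1.0)
})

test_that("shannon_entropy rejects malformed probability vectors, naming the entry", {
  expect_error(shannon_entropy(numeric(0)), class = "habtile_validation_error")
  expect_error(shannon_entropy(c(0.7, -0.2, 0.5)), "entry 2",
               class = "habtile_validation_error")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum",
               class = "habtile_validation_error")
})

test_that("entropy is bounded by log2(k), maximal only at uniformity", {
  set.seed(42)
  for (rep in 1:200) {
    k <- sample(2:8, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    h <- shannon_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log2(k) + 1e-12)
    expect_equal(shannon_entropy(rep(1 / k, k)), log2(k))
    if (max(p) - min(p) > 1e-3) expect_lt(h, log2(k))
  }
})

test_that("merging two types never increases entropy", {
  set.seed(7)
  for (rep in 1:200) {
    k <- sample(3:8, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    ij <- sample(k, 2)
    merged <- c(p[-ij], sum(p[ij]))
    expect_lte(shannon_entropy(merged), shannon_entropy(p) + 1e-12)
  }
})

test_that("combination_count is exact and matches the Cartesian-product oracle", {
  expect_identical(combination_count(2, 5), 32L)
  expect_identical(combination_count(5, 2), 25L)
  expect_identical(combination_count(1, 9), 1L)
  for (comp in 1:4) for (desc in 1:6) {
    expect_identical(combination_count(comp, desc),
                     as.integer(oracle_combinations(comp, desc)))
  }
  expect_error(combination_count(0, 3), class = "habtile_validation_error")
  expect_error(combination_count(2.5, 3), class = "habtile_validation_error")
})

test_that("size_level_count enumerates discrete lattices and refuses continuous ranges", {
  expect_identical(size_level_count(size_dist(8, 56, by = 8)), 7L)
  expect_identical(size_levels(size_dist(8, 56, by = 8)),
                   c(8, 16, 24, 32, 40, 48, 56))
  expect_identical(size_level_count(size_dist(8, 56, by = 48)), 2L)
  expect_identical(size_level_count(size_dist(10)), 1L)
  expect_error(size_level_count(size_dist(8, 56)),
               class = "habtile_unsupported_comparison_error")
})

test_that("size_level_count is non-increasing in the increment over a fixed range", {
  incs <- c(1, 2, 3, 4, 6, 8, 12, 16, 24, 48)
  counts <- vapply(incs, function(b) size_level_count(size_dist(8, 56, by = b)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("size_dist validates its invariants", {
  expect_error(size_dist(10, 5), class = "habtile_validation_error")
  expect_error(size_dist(8, 56, by = 10), "integer multiple",
               class = "habtile_validation_error")
  expect_error(size_dist(-2), class = "habtile_validation_error")
  expect_silent(size_dist(8, 56, by = 8))
})

test_that("surface_area counts planar area plus vertical pit walls", {
  empty <- generate_tile(tile_spec(10, 10,
    types = object_type("p", size_dist(2), size_dist(1), "square"),
    n = 0, arrangement = "ordered"))
  expect_equal(surface_area(empty), 100)

  sq <- generate_tile(tile_spec(10, 10,
    types = object_type("p", size_dist(2), size_dist(1), "square"),
    n = 1, arrangement = "ordered"))
  expect_equal(surface_area(sq), 108)           # 100 + 4*2*1

  circ <- generate_tile(tile_spec(10, 10,
    types = object_type("p", size_dist(2), size_dist(1), "circle"),
    n = 1, arrangement = "ordered"))
  expect_equal(surface_area(circ), 100 + 2 * pi) # 100 + pi*2*1
})

test_that("surface_area agrees with the polygonal-mesh oracle on random designs", {
  for (seed in 1:5) {
    d <- generate_tile(random_spec(seed))
    expect_equal(surface_area(d), oracle_surface_area(d),
                 tolerance = 1e-3)
  }
})

test_that("complexity_report assembles entropy, levels and combinatorics", {
  # fully homogeneous tile: no uncertainty anywhere
  homo <- generate_tile(tile_spec(100, 100,
    types = object_type("p", size_dist(10), size_dist(5), "circle"),
    n = 4, arrangement = "ordered", seed = 1))
  rep <- complexity_report(homo)
  expect_identical(rep$type_entropy, 0)
  expect_true(all(rep$size_levels$levels == 1L))
  expect_identical(rep$combination_count, 1L)

  # 2 components, 5 declared descriptors -> 32 combinations
  two <- generate_tile(one_type_spec(n = 2, seed = 3))
  expect_identical(complexity_report(two, descriptors = 5)$combination_count, 32L)

  # balanced two-type tile carries exactly 1 bit of type entropy
  bal <- generate_tile(two_type_spec(seed = 2))
  expect_equal(complexity_report(bal)$type_entropy, 1.0)
})

test_that("default descriptor count is the number of varying attributes", {
  # two types (1 attribute) + disc footprint 3 levels + pit depth 3 levels
  rep <- complexity_report(generate_tile(two_type_spec(n = 3, seed = 5)))
  expect_identical(rep$descriptors, 3L)
  expect_identical(rep$combination_count, combination_count(3, 3))
})

test_that("entropy comparisons are gated on matching generation rules", {
  rnd <- complexity_report(generate_tile(one_type_spec(arrangement = "random")))
  rnd2 <- complexity_report(generate_tile(one_type_spec(arrangement = "random", seed = 9)))
  ord <- complexity_report(generate_tile(one_type_spec(arrangement = "ordered", buffer = 0)))
  fix <- complexity_report(generate_tile(one_type_spec(
    footprint = size_dist(10), arrangement = "random")))
  expect_true(is_comparable(rnd, rnd2))
  expect_false(is_comparable(rnd, ord))   # ordered vs random: different rules
  expect_false(is_comparable(rnd, fix))   # different distribution kinds
})
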