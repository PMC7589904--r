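test_that("weight-adjusted scores follow the rounding rule", {
  expect_equal(weight_adjusted_score(1.44, 3, 0.5), 4.5)
  expect_equal(weight_adjusted_score(1.10, 3, 1.0), 3)
  expect_equal(weight_adjusted_score(1.0, 3, 1.0), 3)
  expect_equal(weight_adjusted_score(0.75, 2, 1.0), 2)   # tie 1.5 rounds up
  expect_equal(weight_adjusted_score(1.25, 1, 0.5), 1.5) # tie 1.25 rounds up
  expect_error(weight_adjusted_score(-0.5, 3), "positive")
  expect_error(weight_adjusted_score(0, 3), "positive")
})

test_that("deriving from the published model reproduces the published checklist", {
  derived <- derive_checklist(published_model(), default_catalog())
  expect_identical(attr(derived, "provenance"), "derived")
  pub <- published_checklist()
  m <- merge(as.data.frame(derived), as.data.frame(pub),
             by = c("domain", "item_id"), suffixes = c("_derived", "_published"))
  expect_equal(nrow(m), nrow(pub))  # every published item regenerated
  expect_equal(m$weight_derived, m$weight_published)
})

test_that("derivation follows the arithmetic per domain and granularity", {
  cat_loc <- item_catalog(data.frame(
    item_id = c("trigon", "anterior", "dome", "h1", "a1", "n1", "s1"),
    domain = c("location", "location", "location", "history", "access",
               "number", "size"),
    label = c("Trigon", "Anterior wall", "Dome", "h", "a", "n", "s"),
    median_opinion = c(1L, 3L, 4L, 1L, 1L, 1L, 1L)))
  d <- derive_checklist(published_model(), cat_loc)
  loc <- d[d$domain == "location", ]
  expect_equal(loc$weight[match(c("trigon", "anterior", "dome"), loc$item_id)],
               c(1.5, 4.5, 6))

  # 0.99 * k rounds back to k at unit granularity
  cat_his <- item_catalog(data.frame(
    item_id = c(paste0("h", 1:4), "a1", "n1", "s1", "l1"),
    domain = c(rep("history", 4), "access", "number", "size", "location"),
    label = letters[1:8],
    median_opinion = c(1:4, 1L, 1L, 1L, 1L)))
  his <- derive_checklist(published_model(), cat_his)
  expect_equal(his$weight[his$domain == "history"], c(1, 2, 3, 4))

  # identical MOs within a domain give identical weights
  expect_length(unique(d[d$domain == "access", "weight"]), 1L)
})

test_that("the published worked example scores 15", {
  chk <- published_checklist()
  bccs <- score_case(chk, c(history = "No relevant history",
                            access = "Thin bladder wall",
                            number = "1-3 tumours",
                            size = "3-5 cm",
                            location = "Dome"))
  expect_equal(bccs$value, 15)
  expect_equal(unname(bccs$components),
               c(1, 4, 1, 3, 6)[match(names(bccs$components),
                                      c("history", "access", "number",
                                        "size", "location"))])
  expect_equal(bccs$value, sum(bccs$components))
})

test_that("minimal and maximal profiles span the checklist range", {
  chk <- published_checklist()
  lo <- score_case(chk, c(history = "his_none", access = "acc_none",
                          number = "num_1_3", size = "siz_lt3",
                          location = "loc_trigon"))
  expect_equal(lo$value, 5.5)
  hi <- score_case(chk, c(history = "ASA class 4-5",
                          access = "Not amenable to lithotomy position",
                          number = ">10 tumours", size = ">5 cm",
                          location = "Dome"))
  expect_equal(hi$value, 22)
})

test_that("item lookup accepts ids and case-insensitive labels, errors otherwise", {
  chk <- published_checklist()
  by_id <- score_case(chk, c(history = "his_none", access = "acc_none",
                             number = "num_1_3", size = "siz_lt3",
                             location = "loc_dome"))
  by_label <- score_case(chk, c(history = "no relevant history",
                                access = "NO RELEVANT FEATURES",
                                number = "1-3 Tumours", size = "<3 cm",
                                location = "dome"))
  expect_equal(by_id$value, by_label$value)
  expect_error(score_case(chk, c(history = "nonexistent", access = "acc_none",
                                 number = "num_1_3", size = "siz_lt3",
                                 location = "loc_dome")),
               "nonexistent.*history")
  expect_error(score_case(chk, c(history = "his_none")), "access")
})

test_that("replacing an item by a heavier same-domain item never lowers the sum", {
  chk <- published_checklist()
  set.seed(14)
  doms <- c("history", "access", "number", "size", "location")
  for (i in 1:50) {
    case <- vapply(doms, function(d) {
      rows <- chk[chk$domain == d, ]
      rows$item_id[sample.int(nrow(rows), 1)]
    }, "")
    base <- score_case(chk, case)
    d <- sample(doms, 1)
    rows <- chk[chk$domain == d, ]
    heavier <- rows[rows$weight >= base$components[[d]], ]
    case2 <- case
    case2[d] <- heavier$item_id[sample.int(nrow(heavier), 1)]
    expect_gte(score_case(chk, case2)$value, base$value)
  }
})

test_that("checklist sums rank-agree with the probability function (tau >= 0.95)", {
  derived <- derive_checklist(published_model(), grid_catalog())
  grid <- expand.grid(history = 1:5, access = 1:5, number = 1:5, size = 1:5,
                      location = 1:5)
  w <- lapply(c("history", "access", "number", "size", "location"),
              function(d) derived$weight[derived$domain == d])
  names(w) <- c("history", "access", "number", "size", "location")
  bccs <- rowSums(vapply(names(w), function(d) w[[d]][grid[[d]]],
                         numeric(nrow(grid))))
  m <- published_model()
  p <- plogis(m$intercept +
                as.matrix(grid)[, names(m$coefficients)] %*% m$coefficients)
  expect_gte(cor(bccs, as.vector(p), method = "kendall"), 0.95)
})

test_that("scoring scenarios composes with derivation", {
  sc <- generate_scenarios(default_catalog(), 30, seed = 15)
  chk <- derive_checklist(published_model(), default_catalog())
  sums <- score_scenarios(chk, sc)
  expect_length(sums, 30)
  one <- score_case(chk, c(history = sc$history[1], access = sc$access[1],
                           number = sc$number[1], size = sc$size[1],
                           location = sc$location[1]))
  expect_equal(unname(sums[1]), one$value)
  expect_true(all(sums >= 5 & sums <= 22))
})
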