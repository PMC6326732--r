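# Leader-follower graphs: normalisation, sign matrices, subject-vote
# consistency, layering, and between-group flips.

mk_lead <- function(entries, m = 3, labels = letters[1:m]) {
  a <- matrix(0, m, m, dimnames = list(labels, labels))
  for (e in entries) a[e[[1]], e[[2]]] <- e[[3]]
  a[lower.tri(a)] <- 0
  a - t(a)
}

test_that("normalisation and sign matrices preserve antisymmetry and scale", {
  a <- mk_lead(list(list(1, 2, 3), list(1, 3, -0.5), list(2, 3, 1.5)))
  n <- normalize_lead(a)
  expect_equal(max(abs(n)), 1)
  expect_equal(n + t(n), matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(normalize_lead(10 * a), n)
  # hand 3x3 check
  expect_equal(n[1, 2], 1)
  expect_equal(n[1, 3], -0.5 / 3)

  s <- sign_matrix(a)
  expect_true(all(s %in% c(-1, 0, 1)))
  expect_equal(s, sign(a))
  expect_equal(s + t(s), matrix(0, 3, 3), ignore_attr = TRUE)
  expect_error(normalize_lead(matrix(0, 2, 2)), "zero")
})

test_that("consistency graph counts subject votes with run averaging", {
  pairs <- rbind(c(1, 2))
  # 4 subjects, 1 run each: 3 positive votes, 1 negative
  leads <- lapply(c(1, 1, 1, -1), function(s)
    mk_lead(list(list(1, 2, s), list(1, 3, 0.1), list(2, 3, 0.1))))
  g <- consistency_graph(leads, subject = paste0("s", 1:4), pairs = pairs)
  expect_identical(g$edges$from, "a")
  expect_identical(g$edges$to, "b")
  expect_equal(g$edges$weight, 0.75)

  # unanimous agreement: weight 1
  g1 <- consistency_graph(leads[1:3], paste0("s", 1:3), pairs)
  expect_equal(g1$edges$weight, 1)

  # run averaging: a subject with normalised entries +0.3 and -0.1 votes
  # positive once (a dominant third-pair entry fixes the normalisation)
  leads2 <- list(mk_lead(list(list(1, 2, 3), list(1, 3, 10))),
                 mk_lead(list(list(1, 2, -1), list(1, 3, 10))),
                 mk_lead(list(list(1, 2, -1), list(1, 3, 10))))
  g2 <- consistency_graph(leads2, c("s1", "s1", "s2"), pairs)
  expect_equal(g2$edges$weight, 0.5)  # one + vote, one - vote; tie -> a->b
  expect_identical(g2$edges$from, "a")
})

test_that("layer assignment: chain, diamond, and 2-cycle breaking", {
  chain <- list(nodes = c("a", "b", "c"),
                edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                   weight = c(1, 1)))
  expect_identical(assign_layers(chain), c(a = 0L, b = 1L, c = 2L))

  diamond <- list(nodes = c("a", "b", "c", "d"),
                  edges = data.frame(from = c("a", "a", "b", "c"),
                                     to = c("b", "c", "d", "d"),
                                     weight = rep(1, 4)))
  expect_identical(assign_layers(diamond)[["d"]], 2L)

  cyc <- list(nodes = c("a", "b", "c"),
              edges = data.frame(from = c("a", "b", "b"),
                                 to = c("b", "a", "c"),
                                 weight = c(0.9, 0.6, 0.8)))
  expect_message(l <- assign_layers(cyc), "breaking cycle")
  # weaker edge b->a dropped; chain a->b->c remains
  expect_identical(l, c(a = 0L, b = 1L, c = 2L))
})

test_that("flipped edges are exactly the direction-reversed pairs and symmetric", {
  pairs <- rbind(c(1, 2), c(1, 3))
  la <- lapply(1:3, function(i)
    mk_lead(list(list(1, 2, 1), list(1, 3, 1))))
  lb <- lapply(1:3, function(i)
    mk_lead(list(list(1, 2, -1), list(1, 3, 1))))
  ga <- consistency_graph(la, paste0("s", 1:3), pairs)
  gb <- consistency_graph(lb, paste0("s", 1:3), pairs)
  expect_identical(nrow(flipped_edges(ga, ga)), 0L)
  fab <- flipped_edges(ga, gb)
  expect_identical(nrow(fab), 1L)
  expect_setequal(unlist(fab), c("a", "b"))
  # symmetry in arguments
  expect_identical(nrow(flipped_edges(gb, ga)), 1L)

  gc <- consistency_graph(la, paste0("s", 1:3), rbind(c(1, 2)))
  expect_error(flipped_edges(ga, gc), "different pair sets")
})

test_that("low-jitter group shows more consistent edges than high-jitter group", {
  cs <- small_cohort_spec(seed = 13, n_group_a = 6, n_group_b = 6,
                          ordering_jitter_a = 0.05, ordering_jitter_b = 1.2,
                          subject_jitter = 0)
  co <- gen_cohort(cs)
  lm_all <- lapply(co$timecourse, lead_matrix)
  pairs <- pair_index(cs$n_channels)[1:20, ]
  ga <- consistency_graph(lm_all[co$group == "a"],
                          co$subject_id[co$group == "a"], pairs)
  gb <- consistency_graph(lm_all[co$group == "b"],
                          co$subject_id[co$group == "b"], pairs)
  expect_gt(mean(ga$edges$weight), mean(gb$edges$weight))

  # layers are a valid layout: nonnegative with at least one source at 0
  for (g in list(ga, gb)) {
    expect_true(all(g$layers >= 0L))
    expect_true(any(g$layers == 0L))
  }
})
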