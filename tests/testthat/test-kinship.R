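test_that("kinship coefficient matches closed forms", {
  trio <- pedigree(data.frame(
    id = c("f", "m", "c"), sex = c("male", "female", "female"),
    father = c(NA, NA, "f"), mother = c(NA, NA, "m")))
  expect_equal(kinship_coefficient(trio, "f", "c"), 1 / 4)
  expect_equal(kinship_coefficient(trio, "f", "m"), 0)

  cous <- pedigree(cousin_marriage_df())
  expect_equal(kinship_coefficient(cous, "c1", "c2"), 1 / 16)
  expect_equal(inbreeding_coefficient(cous, "x"), 1 / 16)
  expect_equal(inbreeding_coefficient(cous, "c1"), 0)

  sibs <- pedigree(data.frame(
    id = c("f", "m", "a", "b", "k"), sex = c("male", "female", "male",
                                             "female", "male"),
    father = c(NA, NA, "f", "f", "a"), mother = c(NA, NA, "m", "m", "b")))
  expect_equal(kinship_coefficient(sibs, "a", "b"), 1 / 4)
  expect_equal(inbreeding_coefficient(sibs, "k"), 1 / 4)
})

test_that("kinship recursion equals exhaustive path counting on random pedigrees", {
  set.seed(42)
  for (rep in 1:8) {
    df <- random_pedigree_df(n_founders = 4, n_children = sample(5:10, 1))
    ped <- pedigree(df)
    K <- kinship_matrix(ped)
    ids <- sample(df$id, 5)
    for (i in ids) {
      for (j in ids) {
        expect_equal(K[i, j], oracle_kinship(df, i, j),
                     tolerance = 1e-12,
                     label = sprintf("phi(%s,%s) rep %d", i, j, rep))
      }
    }
  }
})

test_that("degree bins classify kinship with closer-bin boundary ties", {
  expect_equal(degree_of_kinship(1 / 4), "1")
  expect_equal(degree_of_kinship(1 / 8), "2")   # half-siblings
  expect_equal(degree_of_kinship(1 / 32), "4")  # great-great-grandparent
  expect_equal(degree_of_kinship(2^-7), "6")
  expect_equal(degree_of_kinship(2^-8), "unrelated")
  expect_equal(degree_of_kinship(0.6), "identical")
  # exact boundary between degrees d and d+1 goes to the closer bin
  expect_equal(degree_of_kinship(2^-2.5), "1")
  expect_equal(degree_of_kinship(2^-3.5), "2")
  expect_equal(degree_of_kinship(2^-1.5), "identical")
  # thresholds strictly decreasing and centred on 2^-(d+1)
  bins <- degree_bins()
  expect_true(all(diff(bins$lower) < 0))
  expect_true(all(bins$lower < bins$centre))
})

test_that("expected_degree distinguishes first-degree types and is 1 for parent-child", {
  sibs <- pedigree(data.frame(
    id = c("f", "m", "a", "b"), sex = c("male", "female", "male", "female"),
    father = c(NA, NA, "f", "f"), mother = c(NA, NA, "m", "m")))
  expect_equal(expected_degree(sibs, "a", "b")$first_degree_type, "sibling")
  expect_equal(expected_degree(sibs, "f", "a")$first_degree_type,
               "parent_offspring")
  expect_error(expected_degree(sibs, "a", "a"), "distinct")

  # on a simulated community without compound relationships, all positive
  # kinships are powers of two and every parent-child pair is degree 1
  com <- simulate_nonextinct(list(n_generations = 4, p_levirate = 0,
                                  p_local_union = 0), seed = 30)
  ped <- com$pedigree
  K <- kinship_matrix(ped)
  phi <- K[upper.tri(K)]
  pos <- phi[phi > 0]
  expect_true(all(abs(log2(pos) - round(log2(pos))) < 1e-9))
  tab <- expected_degree_table(ped, ids = ped$ind$id)
  po <- tab[tab$first_degree_type == "parent_offspring", ]
  expect_true(nrow(po) > 10)
  expect_true(all(po$degree == "1"))
})

test_that("generation assignment layers chains, couples and is relabel-invariant", {
  chain <- pedigree(data.frame(
    id = letters[1:6], sex = rep(c("male", "female"), 3),
    father = c(NA, "a", NA, "c", NA, "e"),
    mother = c(NA, NA, "b", NA, "d", NA)))
  # chain of 5 parent-child links spans generations 1..6
  expect_equal(sort(unique(chain$ind$generation)), 1:6)

  single <- pedigree(data.frame(id = "x", sex = "male"))
  expect_equal(single$ind$generation, 1L)

  two_couples <- pedigree(data.frame(
    id = c("f1", "m1", "f2", "m2", "s", "d", "g"),
    sex = c("male", "female", "male", "female", "male", "female", "male"),
    father = c(NA, NA, NA, NA, "f1", "f2", "s"),
    mother = c(NA, NA, NA, NA, "m1", "m2", "d")))
  expect_equal(two_couples$ind$generation[two_couples$ind$id == "g"], 3L)

  set.seed(7)
  df <- random_pedigree_df(4, 8)
  ped1 <- pedigree(df)
  relab <- df
  map <- setNames(sprintf("Q%02d", sample(nrow(df))), df$id)
  relab$id <- unname(map[df$id])
  relab$father <- ifelse(is.na(df$father), NA, unname(map[df$father]))
  relab$mother <- ifelse(is.na(df$mother), NA, unname(map[df$mother]))
  ped2 <- pedigree(relab)
  expect_equal(ped2$ind$generation[match(map[df$id], ped2$ind$id)],
               ped1$ind$generation[match(df$id, ped1$ind$id)])
})

test_that("identifier and integrity errors are raised", {
  trio <- pedigree(data.frame(
    id = c("f", "m", "c"), sex = c("male", "female", "female"),
    father = c(NA, NA, "f"), mother = c(NA, NA, "m")))
  expect_error(kinship_coefficient(trio, "f", "nope"), "unknown individual")
  cyc <- data.frame(id = c("a", "b"), sex = c("male", "male"),
                    father = c("b", "a"), mother = c(NA, NA))
  expect_error(pedigree(cyc), "cycle")
  badsex <- data.frame(id = c("a", "b"), sex = c("female", "male"),
                       father = c(NA, "a"), mother = c(NA, NA))
  expect_error(pedigree(badsex), "father.*female")
})
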