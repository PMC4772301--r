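make_table <- function(species, prot, dom) {
  n <- length(prot)
  domain_table(data.frame(protein_id = prot, domain_id = dom,
                          start = seq(0, by = 100, length.out = n),
                          end = seq(50, by = 100, length.out = n)),
               species)
}

test_that("domain counting separates occurrences from gene counts", {
  t <- make_table("SC", c("p1", "p1", "p2"), c("d1", "d1", "d1"))
  cm <- count_domains(list(t))
  expect_equal(cm$counts["SC", "d1"], 3L)
  expect_equal(cm$gene_counts["SC", "d1"], 2L)

  t0 <- domain_table(data.frame(protein_id = character(), domain_id = character(),
                                start = integer(), end = integer()), "XT")
  cm2 <- count_domains(list(t, t0))
  expect_true(all(cm2$counts["XT", ] == 0))
  expect_true(all(cm2$gene_counts <= cm2$counts))
})

test_that("domain counting is additive over disjoint protein tables", {
  withr::local_seed(11)
  for (rep in 1:5) {
    t1 <- random_domain_table("SC", n_proteins = 15)
    t2 <- random_domain_table("SC", n_proteins = 15)
    t2$protein_id <- paste0("q", t2$protein_id)
    both <- domain_table(rbind(as.data.frame(t1), as.data.frame(t2)), "SC")
    doms <- union(colnames(count_domains(list(t1))$counts),
                  colnames(count_domains(list(t2))$counts))
    get <- function(tab) {
      v <- setNames(rep(0L, length(doms)), doms)
      cm <- count_domains(list(tab))$counts
      v[colnames(cm)] <- cm[1, ]
      v
    }
    expect_equal(get(both), get(t1) + get(t2))
  }
})

test_that("keyword selection is case-insensitive substring matching", {
  ann <- list(SSF1 = "Symbiosis-related protein",
              SSF2 = "metabolism",
              SSF3 = c("some domain", "innate immune response"),
              SSF4 = "ANTIBACTERIAL response factor")
  sel <- select_keyword_domains(ann)
  expect_true("SSF1" %in% sel)   # "symbio" is a substring, case-folded
  expect_false("SSF2" %in% sel)
  expect_false("SSF3" %in% sel)  # "innate immunity" is not a substring
  expect_true("SSF4" %in% sel)
  expect_error(select_keyword_domains(ann, keywords = c("symbio", "")),
               "empty keyword")
})

test_that("fold-change selection implements the >= t*count inequality", {
  m <- rbind(SC = c(a = 30L, b = 14L, c = 3L, d = 0L, e = 10L),
             XT = c(a = 10L, b = 10L, c = 0L, d = 0L, e = 18L))
  sel <- fold_change_selection(m, "SC", "XT", fold_threshold = 1.5)
  expect_setequal(sel$domain[sel$direction == "SC"], c("a", "c"))  # 30>=15; 3>=0
  expect_setequal(sel$domain[sel$direction == "XT"], "e")          # 18 >= 15
  expect_false("b" %in% sel$domain)  # 14 < 15
  expect_false("d" %in% sel$domain)  # 0 vs 0 never reported
})

test_that("fold-change selection is antisymmetric in the species pair", {
  withr::local_seed(5)
  for (rep in 1:10) {
    m <- matrix(rnbinom(40, mu = 20, size = 2), nrow = 2,
                dimnames = list(c("A", "B"), sprintf("d%02d", 1:20)))
    s1 <- fold_change_selection(m, "A", "B")
    s2 <- fold_change_selection(m, "B", "A")
    expect_setequal(s1$domain[s1$direction == "A"], s2$domain[s2$direction == "A"])
    expect_setequal(s1$domain[s1$direction == "B"], s2$domain[s2$direction == "B"])
  }
})

test_that("Z-scores use the sample standard deviation and flag sigma = 0", {
  bg <- rbind(d1 = c(8, 10, 12), d2 = c(5, 5, 5))
  colnames(bg) <- paste0("s", 1:3)
  z <- zscore_representation(c(d1 = 14, d2 = 7, d3 = 1), bg)
  expect_equal(z$z[z$domain == "d1"], 2.0)        # (14-10)/2
  expect_false(z$scorable[z$domain == "d2"])      # constant background
  expect_false(z$scorable[z$domain == "d3"])      # absent from background
  z0 <- zscore_representation(c(d1 = 10), bg)
  expect_equal(z0$z[1], 0)
})

test_that("species correlation matches the direct product-moment formula", {
  m <- rbind(SC = c(1, 2, 3, 4), AQ = c(2, 4, 5, 9), XT = c(4, 3, 2, 1))
  colnames(m) <- letters[1:4]
  expect_equal(correlate_species(m, "SC", "SC", letters[1:4]), 1.0)
  expect_equal(correlate_species(m, "SC", "XT", letters[1:4]), -1.0)
  x <- m["SC", ]; y <- m["AQ", ]
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_species(m, "SC", "AQ", letters[1:4]), r_direct)
  flat <- rbind(SC = c(1, 1, 1), XT = c(1, 2, 3))
  colnames(flat) <- letters[1:3]
  expect_error(correlate_species(flat, "SC", "XT", letters[1:3]), "variance")
})
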