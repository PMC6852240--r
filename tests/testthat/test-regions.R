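rset <- function(idx) sprintf("A|%d|", idx)

test_that("partners not touching each other give separate single-partner sites", {
  cx <- make_complex(n_res = 36, seed = 2,
                     partners = list(list(theta = c(-60, 60),
                                          window = c(8, 14)),
                                     list(theta = c(120, 240),
                                          window = c(22, 28))))
  sites <- partner_grouping(cx$structure, "A")
  expect_equal(nrow(sites), 2)
  expect_false(any(sites$multi_partner))
  expect_setequal(sites$partner_chains, c("B", "C"))
  # each site equals the interface with its own partner group
  for (i in 1:2) {
    ifc <- detect_interface(cx$structure, "A", strsplit(
      sites$partner_chains[i], "+", fixed = TRUE)[[1]])
    expect_setequal(sites$residues[[i]], ifc$query$res_uid)
  }
})

test_that("partners in mutual contact form one multi-partner site", {
  cx <- make_complex(n_res = 36, seed = 2,
                     partners = list(list(theta = c(-60, 60),
                                          window = c(10, 20)),
                                     list(theta = c(82, 202),
                                          window = c(10, 20))))
  sites <- partner_grouping(cx$structure, "A")
  expect_equal(nrow(sites), 1)
  expect_true(sites$multi_partner[1])
  expect_equal(sites$partner_chains[1], "B+C")
  ifc <- detect_interface(cx$structure, "A", c("B", "C"))
  expect_setequal(sites$residues[[1]], ifc$query$res_uid)
})

test_that("a single partner reduces to plain interface detection", {
  sites <- partner_grouping(CX$structure, "A")
  expect_equal(nrow(sites), 1)
  ifc <- detect_interface(CX$structure, "A", "B")
  expect_setequal(sites$residues[[1]], ifc$query$res_uid)
})

test_that("site mapping follows the global alignment and drops gap-aligned residues", {
  q <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  # identical sequences map identically
  expect_equal(map_site(c(5, 9, 12), q, q), c(5, 9, 12))
  # one insertion in the homolog before the site shifts it back by one
  hom_ins <- paste0(substr(q, 1, 3), "G", substr(q, 4, nchar(q)))
  expect_equal(map_site(c(8, 9, 10), hom_ins, q), c(7, 8, 9))
  # site residues aligned to a gap in the query are dropped
  q_del <- paste0(substr(q, 1, 7), substr(q, 9, nchar(q)))  # query lacks pos 8
  expect_equal(map_site(c(7, 8, 9), q, q_del), c(7, 8))
  # a distant homolog still maps, with a low-identity warning
  far <- paste0(strrep("G", 10), substr(q, 11, nchar(q)))
  expect_warning(map_site(c(15, 16), far, q), "90")
})

test_that("maximum overlap uses the more generous of the two size conventions", {
  expect_equal(overlap_fraction(rset(1:10), rset(4:13)), 0.7)
  expect_equal(overlap_fraction(rset(1:5), rset(6:10)), 0)
  expect_equal(overlap_fraction(rset(1:20), rset(5:10)), 1)  # containment
  expect_equal(overlap_fraction(rset(1:10), rset(6:25)), 0.5)
  expect_error(overlap_fraction(character(0), rset(1)), "non-empty")
})

test_that("region merging follows the 60% rule with the small-site relaxation", {
  # 7/10 overlap (70%) merges into one 13-residue region
  one <- merge_regions(list(a = rset(1:10), b = rset(4:13)))
  expect_equal(nrow(one), 1)
  expect_length(one$residues[[1]], 13)
  expect_setequal(one$members[[1]], c("a", "b"))
  # exactly 60% does not merge (strict >): both survive as regions
  sep <- merge_regions(list(a = rset(1:10), b = rset(5:14)))
  expect_equal(nrow(sep), 2)
  # a four-residue site sharing one residue with a 20-residue site merges
  small <- merge_regions(list(big = rset(1:20), tiny = rset(20:23)))
  expect_equal(nrow(small), 1)
  expect_length(small$residues[[1]], 23)
  # regions of five or fewer residues are dropped at the end
  dropped <- merge_regions(list(a = rset(1:4), b = rset(30:40)))
  expect_equal(nrow(dropped), 1)
  expect_length(dropped$residues[[1]], 11)
})

test_that("merging is idempotent and permutation-invariant", {
  sites <- list(a = rset(1:10), b = rset(4:13), c = rset(30:40),
                d = rset(36:44), e = rset(12:15))
  r1 <- merge_regions(sites)
  # idempotent: feeding the regions back changes nothing
  again <- merge_regions(setNames(r1$residues, paste0("r", r1$region_id)))
  expect_equal(again$residues, r1$residues)
  # permutation-invariant
  for (k in 1:5) {
    perm <- sample(length(sites))
    r2 <- merge_regions(sites[perm])
    expect_equal(r2$residues, r1$residues)
  }
})

test_that("every region is the exact union of its members", {
  set.seed(7)
  for (rep in 1:20) {
    sites <- lapply(seq_len(sample(3:10, 1)), function(i) {
      start <- sample(1:50, 1)
      rset(start:(start + sample(2:12, 1)))
    })
    names(sites) <- paste0("s", seq_along(sites))
    rr <- merge_regions(sites)
    for (i in seq_len(nrow(rr))) {
      u <- sort(unique(unlist(sites[rr$members[[i]]])))
      expect_equal(rr$residues[[i]], u)
      expect_gte(length(rr$members[[i]]), 1)
    }
  }
})
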