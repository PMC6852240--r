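# linear toy chain: single-atom residues every 2.4 A, so residues i and
# i+2 are in 5 A contact across a one-residue gap
line_structure <- function(n = 60, spacing = 2.4) {
  toy_structure(data.frame(chain = "A", resno = seq_len(n),
                           x = seq_len(n) * spacing, y = 0, z = 0))
}

line_table <- function(s, hot, base = 0.05, top = 0.95) {
  surf <- compute_rasa(s)
  ids <- surf$res_uid[surf$surface]
  cv <- compute_cv(s, r_c = 100)
  nip <- tibble::tibble(res_uid = ids,
                        nip = ifelse(ids %in% hot, top, base) +
                          seq_along(ids) * 1e-4)
  assemble_score_table(surf, cv = cv, nip = nip)
}

# score table on the helix complex with a planted NIP signal
planted_table <- function(hot, base = 0.05, top = 0.95) {
  cv <- compute_cv(CX$structure, r_c = 100, chains = "A")
  nip <- tibble::tibble(res_uid = SURF_IDS_A,
                        nip = ifelse(SURF_IDS_A %in% hot, top, base) +
                          seq_along(SURF_IDS_A) * 1e-4)
  assemble_score_table(SURF_A, cv = cv, nip = nip)
}

test_that("a planted high-score cluster yields exactly one seed containing it", {
  s <- line_structure(60)
  hot <- sprintf("A|%d|", 15:20)   # 10% of the surface
  seeds <- detect_seeds(line_table(s, hot), "SC_dock", s)
  expect_equal(nrow(seeds), 1)
  expect_setequal(seeds$residues[[1]], hot)
})

test_that("nearby seed clusters merge and flat profiles give no seed", {
  s <- line_structure(60)
  # two windows separated by one low-scoring residue 4.8 A across the gap
  hot <- sprintf("A|%d|", c(10:12, 14:16))
  seeds <- detect_seeds(line_table(s, hot), "SC_dock", s)
  expect_equal(nrow(seeds), 1)
  expect_true(all(hot %in% seeds$residues[[1]]))
  # two windows far apart stay separate
  hot2 <- sprintf("A|%d|", c(10:12, 40:42))
  seeds2 <- detect_seeds(line_table(s, hot2), "SC_dock", s)
  expect_equal(nrow(seeds2), 2)
  # uniform scores: no margin above the quantile, no seed
  surf <- compute_rasa(s)
  flat <- assemble_score_table(
    surf, cv = compute_cv(s, r_c = 100),
    nip = tibble::tibble(res_uid = surf$res_uid, nip = 0.5))
  expect_equal(nrow(detect_seeds(flat, "SC_dock", s)), 0)
  # clusters below three residues are discarded
  tiny <- detect_seeds(line_table(s, sprintf("A|%d|", c(20, 30, 40, 44, 50, 54))),
                       "SC_dock", s)
  expect_equal(nrow(tiny), 0)
})

test_that("patches grow connected neighbourhoods with fading layer scores", {
  hot <- sprintf("A|%d|", 14:22)
  tab <- planted_table(hot)
  cfg <- surf_config()
  seeds <- detect_seeds(tab, "SC_dock", CX$structure, cfg)
  p <- grow_patches(seeds, tab, "SC_dock", CX$structure, cfg)
  expect_s3_class(p, "surf_patches")
  expect_equal(length(unique(p$patch_id)), 1)
  # every patch residue is a surface residue
  expect_true(all(p$res_uid %in% SURF_IDS_A))
  # the patch is 5 A-connected
  pairs <- surfpatch:::residue_adjacency(CX$structure, unique(p$res_uid), 5)
  comps <- surfpatch:::contact_components(sort(unique(p$res_uid)), pairs)
  expect_length(comps, 1)
  # admission ordering: mean seed score >= extension >= outer
  sc <- surfpatch:::layer_scores(tab, strategy_spec("SC_dock"))
  mean_of <- function(ly) {
    u <- p$res_uid[p$layer == ly]
    if (length(u) == 0) return(NA_real_)
    mean(sc$seed_score[match(u, sc$res_uid)])
  }
  m <- c(mean_of("seed"), mean_of("extension"), mean_of("outer"))
  m <- m[!is.na(m)]
  expect_true(all(diff(m) <= 1e-9))
})

test_that("two seeds on one planted site merge into one patch", {
  hot <- sprintf("A|%d|", c(10:13, 17:20))  # gap of 3 residues
  tab <- planted_table(hot)
  cfg <- surf_config()
  seeds <- detect_seeds(tab, "SC_dock", CX$structure, cfg)
  p <- grow_patches(seeds, tab, "SC_dock", CX$structure, cfg)
  expect_equal(length(unique(p$patch_id)), 1)
})

test_that("the iterative consensus is deterministic and surface-restricted", {
  cv <- compute_cv(CX$structure, r_c = 100, chains = "A")
  tj <- conservation_to_residues(compute_conservation(POOL_A, seed = 5),
                                 CX$structure, "A")
  tab <- assemble_score_table(SURF_A, cv = cv, tjet = tj)
  cfg <- surf_config()
  p1 <- predict_patches(tab, "SC_cons", CX$structure, cfg, pool = POOL_A,
                        chain = "A", seed = 9)
  p2 <- predict_patches(tab, "SC_cons", CX$structure, cfg, pool = POOL_A,
                        chain = "A", seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$res_uid %in% SURF_IDS_A))
  # consensus hit counts respect the >= min_hits rule
  expect_true(all(p1$hits >= cfg$min_hits))
  expect_true(all(p1$hits <= cfg$n_iter))
  # final patches are 5 A-connected
  for (pid in unique(p1$patch_id)) {
    u <- sort(p1$res_uid[p1$patch_id == pid])
    comps <- surfpatch:::contact_components(
      u, surfpatch:::residue_adjacency(CX$structure, u, 5))
    expect_length(comps, 1)
  }
})

test_that("deterministic-score strategies reduce to a single run", {
  hot <- sprintf("A|%d|", 14:22)
  tab <- planted_table(hot)
  cfg <- surf_config()
  cons <- predict_patches(tab, "SC_dock", CX$structure, cfg, seed = 1)
  single <- grow_patches(detect_seeds(tab, "SC_dock", CX$structure, cfg),
                         tab, "SC_dock", CX$structure, cfg)
  expect_setequal(cons$res_uid, single$res_uid)
})

test_that("strategies only read the scores they are defined on", {
  cv <- compute_cv(CX$structure, r_c = 100, chains = "A")
  nip <- compute_nip(compute_ip(filter_poses(POSES_A),
                                residues = SURF_IDS_A))
  # SC_geom must work with conservation and docking absent
  geom_tab <- assemble_score_table(SURF_A, cv = cv)
  expect_silent(ignore <- detect_seeds(geom_tab, "SC_geom", CX$structure))
  # SC_dock must work with conservation absent and ignore pc/cv
  dock_tab <- assemble_score_table(SURF_A, cv = cv, nip = nip)
  dock_tab$pc <- NA_real_
  dock_tab$cv <- NA_real_
  expect_silent(ignore <- detect_seeds(dock_tab, "SC_dock", CX$structure))
  # conservation-driven strategies fail fast without T_JET
  expect_error(detect_seeds(geom_tab, "SC_cons", CX$structure), "tjet")
  expect_error(detect_seeds(dock_tab, "SC_notLig", CX$structure), "tjet")
  # SC_dock fails fast without docking scores
  expect_error(detect_seeds(geom_tab, "SC_dock", CX$structure), "nip")
})
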