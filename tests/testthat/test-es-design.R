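test_that("base-pair classification follows the strong/weak rules", {
  expect_equal(classify_pair("G", "C"), "strong")
  expect_equal(classify_pair("A", "U"), "strong")
  expect_equal(classify_pair("G", "U"), "strong")  # wobble counts strong
  expect_equal(classify_pair("U", "G"), "strong")
  expect_equal(classify_pair("G", "A"), "weak")
  expect_equal(classify_pair("A", "G"), "weak")
  expect_equal(classify_pair("G", "G"), "weak")
  expect_equal(classify_pair("U", "U"), "weak")
  expect_equal(classify_pair("C", "U"), "other")
  expect_equal(classify_pair("A", "A"), "other")
  expect_equal(classify_pair(c("G", "C"), c("C", "U")),
               c("strong", "other"))
  expect_error(classify_pair("G", "T"), "A, C, G, U")
})

test_that("register shifts re-pair deterministically and conserve bases", {
  gs <- data.frame(five = c("G", "G", "A"), three = c("C", "U", "U"))

  # null shift is the identity
  id <- register_shift(gs, 0)
  expect_equal(id$es_pairs$five, gs$five)
  expect_equal(id$es_pairs$three, gs$three)
  expect_equal(nrow(id$displaced), 0)

  # hand-enumerated +1 shift: three[i] re-pairs five[i+1];
  # bottom 5' base leaves to the terminal, top 3' base joins the loop
  t1 <- register_shift(gs, "type1")
  expect_equal(t1$es_pairs$five, c("G", "A"))
  expect_equal(t1$es_pairs$three, c("C", "U"))
  expect_equal(t1$es_pairs$klass, c("strong", "strong"))
  expect_equal(t1$displaced$base[t1$displaced$fate == "terminal"], "G")
  expect_equal(t1$displaced$base[t1$displaced$fate == "loop"], "U")

  # nucleotide content is conserved under every mode
  for (mode in c("type1", "type2", "type3", "type4")) {
    rs <- register_shift(gs, mode)
    kept <- c(rs$es_pairs$five, rs$es_pairs$three, rs$displaced$base)
    expect_equal(sort(kept), sort(c(gs$five, gs$three)))
  }

  # +1 then -1 restores the interior pair (the middle pair of the
  # original stem survives both shifts unchanged)
  fwd <- register_shift(gs, 1L)
  back <- register_shift(fwd$es_pairs[, c("five", "three")], -1L)
  expect_equal(back$es_pairs$five, gs$five[2])
  expect_equal(back$es_pairs$three, gs$three[2])

  expect_error(register_shift(gs, 4L), "exceeds stem length")
})

test_that("enumeration counts match closed forms and a brute-force oracle", {
  # single position: six strong pairs
  one <- enumerate_stems(hairpin_spec(stem_len = 1),
                         apply_triplet = FALSE, apply_es = FALSE)
  expect_equal(one$n_raw, 6)

  two <- enumerate_stems(hairpin_spec(stem_len = 2),
                         apply_triplet = FALSE, apply_es = FALSE)
  expect_equal(two$n_raw, 36)

  # stem_len 3 under full constraints versus an independent naive oracle
  lib <- enumerate_stems(hairpin_spec(stem_len = 3))
  strong <- c("AU", "UA", "GC", "CG", "GU", "UG")
  weak <- c("GG", "UU", "GA", "AG")
  oracle <- character(0)
  for (p1 in strong) for (p2 in strong) for (p3 in strong) {
    pairs <- c(p1, p2, p3)  # bottom to top
    trip <- c(paste(p2, p1, "term:G"), paste(p3, p2, p1),
              paste("cap:GA", p3, p2))
    if (anyDuplicated(trip)) next
    # type1 ES: three[i] pairs five[i+1], i = 1, 2
    es <- c(paste0(substr(p2, 1, 1), substr(p1, 2, 2)),
            paste0(substr(p3, 1, 1), substr(p2, 2, 2)))
    if (any(!es %in% c(strong, weak))) next
    if (sum(es %in% weak) > 1) next
    oracle <- c(oracle, paste(pairs, collapse = ""))
  }
  got <- vapply(lib$candidates, function(cd)
    paste(paste0(cd$gs_pairs$five, cd$gs_pairs$three), collapse = ""),
    character(1))
  expect_setequal(got, oracle)
})

test_that("every stem position carries a distinct triplet signature", {
  lib <- enumerate_stems(hairpin_spec(stem_len = 3))
  for (cd in lib$candidates[seq_len(min(25, length(lib$candidates)))]) {
    expect_false(anyDuplicated(cd$triplet_signatures) > 0)
    kl <- cd$es_pairs$klass
    expect_true(all(kl != "other"))
    expect_lte(sum(kl == "weak"), 1)
    expect_true(all(cd$gs_pairs$klass == "strong"))
  }
})

test_that("the bundled backend scores stems additively and symmetrically", {
  be <- nn_energy_backend()
  # identical structure scores identically: ddG of a null shift is 0
  gs <- data.frame(five = c("G", "C", "G"), three = c("C", "G", "C"))
  expect_equal(be$score(gs, 4) - be$score(gs, 4), 0)

  # hand summation against the bundled table
  helix <- data.frame(five = c("G", "G", "A"), three = c("C", "U", "U"))
  expected <- unname(be$stacks["GC,GU"] + be$stacks["GU,AU"]) +
    be$loop_init[["4"]]
  expect_equal(be$score(helix, 4), expected)

  # two-strand reading symmetry of the stack table
  rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (key in names(be$stacks)) {
    pq <- strsplit(key, ",")[[1]]
    mirror <- paste(rev2(pq[2]), rev2(pq[1]), sep = ",")
    expect_equal(unname(be$stacks[key]), unname(be$stacks[mirror]))
  }

  # a weak pair interrupts stacking and costs the fixed penalty
  wk <- data.frame(five = c("G", "G"), three = c("C", "G"))
  expect_equal(be$score(wk, 4),
               be$weak_pair_penalty + be$loop_init[["4"]])
  expect_error(be$score(data.frame(five = "C", three = "U"), 4), "other")
})

test_that("candidate scoring reports the GS-to-ES gap with sign", {
  be <- nn_energy_backend()
  lib <- enumerate_stems(hairpin_spec(stem_len = 3))
  cd <- score_candidate(lib$candidates[[1]], be)
  # independent recomputation
  loop_grow <- sum(cd$displaced$fate == "loop")
  expected <- be$score(cd$es_pairs, 4 + loop_grow) -
    be$score(cd$gs_pairs, 4)
  expect_equal(cd$ddG, expected)
  # an ES more stable than the GS flags an inversion
  stub <- lib$candidates[[1]]
  inv_backend <- structure(list(
    name = "stub",
    score = function(pairs, loop_size) -nrow(pairs)),
    class = "energy_backend")
  inv <- score_candidate(stub, inv_backend)
  expect_true(attr(inv, "inverted") == (inv$ddG < 0))
})

test_that("the design filter applies the threshold and rank conditions", {
  lib <- enumerate_stems(hairpin_spec(stem_len = 3))
  ds <- design_filter(lib, threshold = 3)
  expect_s3_class(ds, "design_set")
  # brute-force oracle over the same scored set
  be <- nn_energy_backend()
  scored <- lapply(lib$candidates, score_candidate, backend = be)
  keys <- function(cands) vapply(cands, function(cd)
    paste(paste0(cd$gs_pairs$five, cd$gs_pairs$three), collapse = ""),
    character(1))
  alt_min <- vapply(scored, function(cd) {
    a <- hairpinES:::.alternative_ddGs(cd, be)
    if (length(a)) min(a) else Inf
  }, numeric(1))
  ddg <- vapply(scored, function(cd) cd$ddG, numeric(1))
  oracle_keys <- keys(scored)[ddg <= 3 & alt_min >= ddg]
  expect_setequal(keys(ds$accepted), oracle_keys)

  # accepted list is sorted by ddG ascending
  got_ddg <- vapply(ds$accepted, function(cd) cd$ddG, numeric(1))
  expect_true(all(diff(got_ddg) >= 0))

  # every accepted design re-verifies the three constraints directly
  for (cd in ds$accepted) {
    expect_true(all(classify_pair(cd$gs_pairs$five,
                                  cd$gs_pairs$three) == "strong"))
    expect_false(anyDuplicated(cd$triplet_signatures) > 0)
    kl <- classify_pair(cd$es_pairs$five, cd$es_pairs$three)
    expect_true(all(kl != "other") && sum(kl == "weak") <= 1)
    expect_lte(cd$ddG, 3)
    expect_gte(cd$alt_ddG_min, cd$ddG)
  }

  # inclusive threshold: a preset gap of exactly 3.0 kcal/mol passes
  # when no alternative undercuts it (crafted backend keeps every
  # alternative 10 kcal/mol above its parent GS)
  alt_high <- structure(list(name = "alt_high",
                             score = function(pairs, loop_size)
                               -10 * nrow(pairs)),
                        class = "energy_backend")
  cd <- lib$candidates[[1]]
  cd$ddG <- 3.0
  ds2 <- design_filter(list(cd), threshold = 3, backend = alt_high)
  expect_equal(length(ds2$accepted), 1)

  # rank condition: an alternative with a lower gap rejects the design
  # (backend scoring by pair count makes the 1-pair double-shift
  # alternative the most stable excited structure)
  cd2 <- lib$candidates[[1]]
  by_count <- structure(list(name = "by_count",
                             score = function(pairs, loop_size)
                               nrow(pairs)),
                        class = "energy_backend")
  ds3 <- design_filter(list(cd2), threshold = 30, backend = by_count)
  expect_equal(length(ds3$accepted), 0)
})

test_that("the 3 kcal/mol gate corresponds to the RD detection floor", {
  expect_equal(pop_from_dG(3, 283.15), 0.005, tolerance = 0.15)
})
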