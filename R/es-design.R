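#' Strong/weak classification of base pairs
#'
#' The design rules partition base pairs into "strong" (Watson-Crick
#' pairs and G.U wobbles: A-U, U-A, G-C, C-G, G.U, U.G), "weak"
#' (the G.G, U.U, G.A and A.G non-canonical pairs) and "other"
#' (everything else, disallowed in both GS and ES stems).
#'
#' @param five_prime_base,three_prime_base Character vectors of
#'   nucleotides in `A`, `C`, `G`, `U`; the pair is read 5' base first.
#' @return Character vector in `c("strong", "weak", "other")`.
#' @examples
#' classify_pair("G", "C")  # strong
#' classify_pair("G", "A")  # weak
#' classify_pair("C", "U")  # other
#' @export
classify_pair <- function(five_prime_base, three_prime_base) {
  ok <- c("A", "C", "G", "U")
  if (!all(five_prime_base %in% ok) || !all(three_prime_base %in% ok))
    stop("bases must be one of A, C, G, U")
  p <- paste0(five_prime_base, three_prime_base)
  ifelse(p %in% .strong_pairs, "strong",
         ifelse(p %in% .weak_pairs, "weak", "other"))
}

.strong_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
.weak_pairs   <- c("GG", "UU", "GA", "AG")

#' Hairpin design specification
#'
#' @param loop_seq Tetraloop sequence (informational; its length sets the
#'   GS loop size). Default `"GCAA"`.
#' @param stem_len Number of base pairs in the variable stem, default 5.
#' @param closing_mismatch Two-character token for the non-canonical pair
#'   capping the stem below the loop (default `"GA"`), used as the
#'   context token in triplet signatures.
#' @param shift_mode One of `"type1"` (+1 register, 5'->3' slide),
#'   `"type2"` (-1 register), `"type3"` (+2 register), `"type4"` (+1
#'   register in a lower stem next to a bulge).
#' @param dangling_5prime Optional 5'-dangling nucleotide (e.g. `"G"`
#'   appended for transcription efficiency); context token only.
#' @return List of class `"hairpin_spec"`.
#' @export
hairpin_spec <- function(loop_seq = "GCAA", stem_len = 5,
                         closing_mismatch = "GA",
                         shift_mode = c("type1", "type2", "type3", "type4"),
                         dangling_5prime = "G") {
  shift_mode <- match.arg(shift_mode)
  stopifnot(stem_len >= 1)
  shift <- .mode_shift(shift_mode)
  if (abs(shift) > stem_len)
    stop("register shift magnitude exceeds stem length")
  structure(list(loop_seq = loop_seq, stem_len = stem_len,
                 closing_mismatch = closing_mismatch,
                 shift_mode = shift_mode,
                 dangling_5prime = dangling_5prime),
            class = "hairpin_spec")
}

.mode_shift <- function(mode) {
  switch(mode, type1 = 1L, type2 = -1L, type3 = 2L, type4 = 1L,
         stop("unknown shift mode: ", mode))
}

#' Re-pair a stem after a register shift
#'
#' A stem of `n` pairs is held as two strands read bottom (terminal side)
#' to top (loop side): `five[i]` pairs `three[i]` in the GS. A positive
#' register shift of `k` (the 3' strand sliding towards the loop, as in
#' type 1/3/4 switching) re-pairs `three[i]` with `five[i + k]`; the
#' bottom `k` bases of the 5' strand join the terminal (or bulge) region
#' and the top `k` bases of the 3' strand join the loop, which grows
#' accordingly (tetraloop to pentaloop for `k = 1`). A negative shift
#' mirrors this (type 2). Nucleotide content is conserved; interior pairs
#' are restored exactly by applying the opposite shift.
#'
#' @param gs_pairs Data frame with columns `five` and `three` (character,
#'   one row per pair, bottom to top) as produced by [enumerate_stems()],
#'   or a list with those elements.
#' @param mode A shift mode name (see [hairpin_spec()]) or an integer
#'   register shift.
#' @return List with `es_pairs` (data frame `five`, `three`, `klass`),
#'   `displaced` (data frame `base`, `strand`, `fate` in
#'   `c("loop", "terminal")`), and `shift`.
#' @examples
#' gs <- data.frame(five = c("G", "G", "A"), three = c("C", "U", "U"))
#' register_shift(gs, "type1")
#' @export
register_shift <- function(gs_pairs, mode) {
  five <- gs_pairs$five
  three <- gs_pairs$three
  n <- length(five)
  stopifnot(n >= 1L, length(three) == n)
  k <- if (is.numeric(mode)) as.integer(mode) else .mode_shift(mode)
  if (abs(k) > n) stop("register shift magnitude exceeds stem length")
  if (k == 0L) {
    es <- data.frame(five = five, three = three)
  } else if (k > 0L) {
    idx <- seq_len(n - k)
    es <- data.frame(five = five[idx + k], three = three[idx])
    displaced <- rbind(
      if (k >= 1L) data.frame(base = five[seq_len(k)], strand = "5p",
                              fate = "terminal"),
      data.frame(base = three[n - seq_len(k) + 1L], strand = "3p",
                 fate = "loop"))
  } else {
    m <- -k
    idx <- seq_len(n - m)
    es <- data.frame(five = five[idx], three = three[idx + m])
    displaced <- rbind(
      data.frame(base = three[seq_len(m)], strand = "3p",
                 fate = "terminal"),
      data.frame(base = five[n - seq_len(m) + 1L], strand = "5p",
                 fate = "loop"))
  }
  if (k == 0L)
    displaced <- data.frame(base = character(), strand = character(),
                            fate = character())
  es$klass <- classify_pair(es$five, es$three)
  list(es_pairs = es, displaced = displaced, shift = k)
}

# triplet signature of each stem position: (pair above, pair, pair below),
# with context tokens at the termini; pair strings are 5'-oriented so
# strandedness is inherent
.triplet_signatures <- function(pairs, top_context, bottom_context) {
  n <- length(pairs)
  above <- c(pairs[-1], top_context)
  below <- c(bottom_context, pairs[-n])
  paste(above, pairs, below, sep = "|")
}

#' Enumerate stem candidates for a hairpin design
#'
#' Exhausts all combinations of strong base pairs over the stem
#' positions, then (optionally) applies the two remaining design
#' constraints: every stem position must sit in a unique base-pair
#' triplet (so imino resonances resolve in the 2D spectrum), and the ES
#' obtained by the requested register shift may contain at most one weak
#' pair with all others strong. Output order is deterministic
#' (lexicographic in the bottom-to-top pair sequence).
#'
#' @param spec A [hairpin_spec()].
#' @param apply_triplet Apply the BP-triplet uniqueness constraint
#'   (default `TRUE`).
#' @param apply_es Apply the ES pairing constraint (default `TRUE`).
#' @param triplet_scope `"all"` (default) checks uniqueness for every
#'   stem position; `"gu_only"` restricts the check to positions whose
#'   pair carries an imino-bearing G or U facing the helix interior
#'   (all six strong pairs do, so this only matters for custom pair sets).
#' @return List of class `"stem_library"`: `candidates` (list of
#'   `"stem_candidate"` objects), `spec`, and counts per filtering stage.
#' @examples
#' lib <- enumerate_stems(hairpin_spec(stem_len = 2))
#' lib$n_raw      # 36 = 6^2 strong-pair combinations
#' @export
enumerate_stems <- function(spec, apply_triplet = TRUE, apply_es = TRUE,
                            triplet_scope = c("all", "gu_only")) {
  stopifnot(inherits(spec, "hairpin_spec"))
  triplet_scope <- match.arg(triplet_scope)
  n <- spec$stem_len
  grid <- expand.grid(rep(list(.strong_pairs), n),
                      stringsAsFactors = FALSE)
  # lexicographic order in bottom..top pair strings
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  n_raw <- nrow(grid)
  shift <- .mode_shift(spec$shift_mode)
  top_ctx <- paste0("cap:", spec$closing_mismatch)
  bot_ctx <- if (spec$shift_mode == "type4") "bulge"
  else paste0("term:", spec$dangling_5prime)

  keep <- logical(n_raw)
  cands <- vector("list", n_raw)
  n_triplet <- 0L
  for (r in seq_len(n_raw)) {
    pairs <- as.character(grid[r, ])
    sig <- .triplet_signatures(pairs, top_ctx, bot_ctx)
    check <- if (triplet_scope == "all") seq_len(n)
    else which(grepl("G|U", pairs))
    if (apply_triplet && anyDuplicated(sig[check])) next
    n_triplet <- n_triplet + 1L
    gs <- data.frame(five = substr(pairs, 1, 1),
                     three = substr(pairs, 2, 2))
    rs <- register_shift(gs, shift)
    if (apply_es) {
      kl <- rs$es_pairs$klass
      if (any(kl == "other") || sum(kl == "weak") > 1L) next
    }
    keep[r] <- TRUE
    cands[[r]] <- structure(list(
      gs_pairs = cbind(gs, klass = classify_pair(gs$five, gs$three)),
      es_pairs = rs$es_pairs, displaced = rs$displaced,
      triplet_signatures = sig, shift_mode = spec$shift_mode,
      spec = spec, ddG = NA_real_, rank_ok = NA
    ), class = "stem_candidate")
  }
  structure(list(candidates = cands[keep], spec = spec,
                 n_raw = n_raw, n_after_triplet = n_triplet,
                 n_final = sum(keep)),
            class = "stem_library")
}

#' @export
print.stem_library <- function(x, ...) {
  cat("Stem library (", x$spec$shift_mode, ", stem_len = ",
      x$spec$stem_len, "): ", x$n_raw, " strong-pair stems -> ",
      x$n_after_triplet, " with unique triplets -> ", x$n_final,
      " with admissible ES\n", sep = "")
  invisible(x)
}

#' Bundled approximate nearest-neighbour energy backend
#'
#' A simplified additive stacking model: helix free energy is the sum of
#' nearest-neighbour stack terms over adjacent strong pairs plus a
#' hairpin-loop initiation penalty and a fixed destabilization for each
#' weak pair (which also interrupts stacking). Watson-Crick stack values
#' follow the standard optical-melting nearest-neighbour set; wobble
#' stacks are coarse approximations. The backend is deliberately
#' approximate -- it ranks candidate structures for the design filter and
#' is not a substitute for a full secondary-structure energy model.
#'
#' @param weak_pair_penalty Destabilization per weak pair, kcal/mol
#'   (default 1.5).
#' @return List of class `"energy_backend"` with a `score(pairs,
#'   loop_size)` function (pairs: data frame `five`/`three` bottom to
#'   top), a `name`, and the parameter tables.
#' @examples
#' be <- nn_energy_backend()
#' gs <- data.frame(five = c("G", "C", "G"), three = c("C", "G", "C"))
#' be$score(gs, loop_size = 4)
#' @export
nn_energy_backend <- function(weak_pair_penalty = 1.5) {
  stacks <- .nn_stack_table()
  loops <- c(`3` = 5.4, `4` = 5.6, `5` = 5.7, `6` = 5.4, `7` = 6.0,
             `8` = 5.5, `9` = 6.0)
  score <- function(pairs, loop_size) {
    p <- paste0(pairs$five, pairs$three)
    kl <- classify_pair(pairs$five, pairs$three)
    if (any(kl == "other"))
      stop("cannot score a stem containing 'other' pairs: ",
           paste(p[kl == "other"], collapse = ", "))
    e <- 0
    n <- length(p)
    if (n >= 2L) for (i in seq_len(n - 1L)) {
      if (kl[i] == "strong" && kl[i + 1L] == "strong") {
        key <- paste(p[i], p[i + 1L], sep = ",")
        v <- stacks[key]
        if (is.na(v))
          stop("no stacking parameter for stack ", key)
        e <- e + unname(v)
      }
    }
    e <- e + weak_pair_penalty * sum(kl == "weak")
    ls <- as.character(loop_size)
    lp <- if (ls %in% names(loops)) loops[[ls]]
    else loops[["9"]] + 1.75 * physical_constants()$R * 310 *
      log(loop_size / 9)  # Jacobson-Stockmayer extrapolation
    e + lp
  }
  structure(list(name = "nn_approx", score = score, stacks = stacks,
                 loop_init = loops,
                 weak_pair_penalty = weak_pair_penalty),
            class = "energy_backend")
}

# stack table keyed "lower,upper" where each pair is written 5' base
# first; value = free-energy increment (kcal/mol, 37 degC scale).
# WC/WC seeds are the standard nearest-neighbour set; wobble seeds are
# approximate. The two-strand reading symmetry
# stack(p, q) = stack(rev(q), rev(p)) is closed programmatically.
.nn_stack_table <- function() {
  seeds <- c(
    # WC lower, WC upper (canonical 10)
    "AU,AU" = -0.93, "AU,UA" = -1.10, "UA,AU" = -1.33, "AU,CG" = -2.24,
    "AU,GC" = -2.08, "UA,CG" = -2.35, "UA,GC" = -2.11, "CG,CG" = -3.26,
    "CG,GC" = -2.36, "GC,CG" = -3.42,
    # wobble-containing stacks (approximate)
    "GU,AU" = -1.27, "GU,UA" = -1.36, "GU,CG" = -2.11, "GU,GC" = -1.53,
    "UG,AU" = -1.00, "UG,UA" = -0.55, "UG,CG" = -1.41, "UG,GC" = -2.51,
    "GU,GU" = -0.50, "GU,UG" = +0.30, "UG,GU" = -1.20)
  rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  out <- seeds
  for (key in names(seeds)) {
    pq <- strsplit(key, ",", fixed = TRUE)[[1]]
    mk <- paste(rev2(pq[2]), rev2(pq[1]), sep = ",")
    if (!mk %in% names(out)) out[mk] <- seeds[[key]]
  }
  out
}

#' Score a stem candidate's GS-to-ES free-energy gap
#'
#' `ddG = E(ES structure) - E(GS structure)` under the supplied energy
#' backend, including the loop-size change caused by the register shift
#' (displaced loop-side nucleotides enlarge the loop). A negative value
#' means the nominal ES is more stable than the nominal GS (a GS/ES
#' inversion), which is reported via the `"inverted"` attribute.
#'
#' @param cand A `"stem_candidate"` (from [enumerate_stems()]).
#' @param backend An energy backend (default [nn_energy_backend()]).
#' @param gs_loop_size Loop size of the GS (default: tetraloop, 4).
#' @return The candidate with `ddG` filled in.
#' @export
score_candidate <- function(cand, backend = nn_energy_backend(),
                            gs_loop_size = 4) {
  stopifnot(inherits(cand, "stem_candidate"))
  loop_grow <- sum(cand$displaced$fate == "loop")
  e_gs <- backend$score(cand$gs_pairs, gs_loop_size)
  e_es <- backend$score(cand$es_pairs, gs_loop_size + loop_grow)
  cand$ddG <- e_es - e_gs
  attr(cand, "inverted") <- cand$ddG < 0
  cand
}

# bounded alternative-structure scan: register shifts of magnitude <= 2
# in both directions (excluding the designed one and the identity) plus
# terminal- and top-pair-melted variants of the GS
.alternative_ddGs <- function(cand, backend, gs_loop_size = 4) {
  gs <- cand$gs_pairs[, c("five", "three")]
  n <- nrow(gs)
  e_gs <- backend$score(gs, gs_loop_size)
  designed <- .mode_shift(cand$shift_mode)
  alts <- numeric(0)
  for (k in setdiff(c(-2L, -1L, 1L, 2L), designed)) {
    if (abs(k) >= n) next
    rs <- register_shift(gs, k)
    kl <- rs$es_pairs$klass
    if (any(kl == "other")) next  # not a formable alternative helix
    loop_grow <- sum(rs$displaced$fate == "loop")
    alts <- c(alts, backend$score(rs$es_pairs, gs_loop_size + loop_grow) - e_gs)
  }
  if (n >= 2L) {
    # melt the terminal (bottom) pair
    alts <- c(alts, backend$score(gs[-1L, ], gs_loop_size) - e_gs)
    # melt the loop-closing (top) pair: loop grows by 2
    alts <- c(alts, backend$score(gs[-n, ], gs_loop_size + 2) - e_gs)
  }
  alts
}

#' Filter scored candidates by the ES design rules
#'
#' A candidate is accepted when (a) the designed ES lies within
#' `threshold` kcal/mol of the GS (inclusive; 3 kcal/mol corresponds to
#' roughly the 0.5% population floor detectable by relaxation
#' dispersion), and (b) no scanned alternative structure undercuts the
#' designed ES (`min(ddG_alternatives) >= ddG_designed`). Accepted
#' designs are returned sorted by `ddG` ascending, so the first element
#' is the construct of choice.
#'
#' @param cands A `"stem_library"` or list of stem candidates (scored or
#'   not; unscored candidates are scored with `backend`).
#' @param threshold Acceptance threshold in kcal/mol (default 3).
#' @param backend Energy backend for scoring and the alternative scan.
#' @param gs_loop_size GS loop size (default 4).
#' @return List of class `"design_set"`: `accepted` (sorted candidate
#'   list, each with `rank_ok = TRUE` and an `alt_ddG_min` field),
#'   `n_scored`, `threshold`.
#' @export
design_filter <- function(cands, threshold = 3,
                          backend = nn_energy_backend(),
                          gs_loop_size = 4) {
  if (inherits(cands, "stem_library")) cands <- cands$candidates
  scored <- lapply(cands, function(cd) {
    if (is.na(cd$ddG)) cd <- score_candidate(cd, backend, gs_loop_size)
    cd$alt_ddG_min <- {
      a <- .alternative_ddGs(cd, backend, gs_loop_size)
      if (length(a)) min(a) else Inf
    }
    cd$rank_ok <- cd$alt_ddG_min >= cd$ddG
    cd
  })
  acc <- Filter(function(cd) cd$ddG <= threshold && cd$rank_ok, scored)
  acc <- acc[order(vapply(acc, function(cd) cd$ddG, numeric(1)))]
  structure(list(accepted = acc, n_scored = length(scored),
                 threshold = threshold),
            class = "design_set")
}

#' @export
print.design_set <- function(x, ...) {
  cat("Design filter: ", length(x$accepted), "/", x$n_scored,
      " candidates accepted at ddG <= ", x$threshold, " kcal/mol\n",
      sep = "")
  if (length(x$accepted)) {
    top <- x$accepted[[1]]
    cat("  best: ", paste0(top$gs_pairs$five, top$gs_pairs$three,
                           collapse = " "),
        "  ddG = ", round(top$ddG, 2), " kcal/mol\n", sep = "")
  }
  invisible(x)
}

#' @export
print.stem_candidate <- function(x, ...) {
  cat("Stem candidate (", x$shift_mode, ")\n", sep = "")
  cat("  GS:", paste0(x$gs_pairs$five, x$gs_pairs$three, collapse = " "),
      "\n  ES:", paste0(x$es_pairs$five, x$es_pairs$three, collapse = " "),
      "\n")
  if (!is.na(x$ddG)) cat("  ddG =", round(x$ddG, 3), "kcal/mol\n")
  invisible(x)
}
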