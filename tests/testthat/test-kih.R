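test_that("side-chain centers follow the SOCKET working definition", {
  p <- helix_params(radius = 5, pitch = -200,
                    sequence = "GAIL", register = "abcd")
  spec <- assembly_spec("basic", "coiled_coil", 2, list(p))
  aa <- place_sidechains(build_assembly(spec)$model)
  ctr <- sidechain_centers(aa)
  # Gly -> CA position
  gly_ca <- aa[aa$chain == "A" & aa$res_num == 1 & aa$atom == "CA", ]
  gly_ctr <- ctr[ctr$chain == "A" & ctr$res_num == 1, ]
  expect_equal(c(gly_ctr$x, gly_ctr$y, gly_ctr$z),
               c(gly_ca$x, gly_ca$y, gly_ca$z))
  # Ala -> CB position
  ala_cb <- aa[aa$chain == "A" & aa$res_num == 2 & aa$atom == "CB", ]
  ala_ctr <- ctr[ctr$chain == "A" & ctr$res_num == 2, ]
  expect_equal(c(ala_ctr$x, ala_ctr$y, ala_ctr$z),
               c(ala_cb$x, ala_cb$y, ala_cb$z))
  # multi-atom side chain -> arithmetic mean of heavy atoms incl. CB
  leu <- aa[aa$chain == "A" & aa$res_num == 4 &
              !(aa$atom %in% c("N", "CA", "C", "O")), ]
  leu_ctr <- ctr[ctr$chain == "A" & ctr$res_num == 4, ]
  expect_equal(c(leu_ctr$x, leu_ctr$y, leu_ctr$z),
               c(mean(leu$x), mean(leu$y), mean(leu$z)))
})

test_that("knob detection matches the brute-force oracle on the dimer", {
  aa <- canonical_dimer_allatom()
  kih <- find_kih(aa)
  ref <- oracle_kih(as.data.frame(aa))
  got <- unique(paste(kih$knob_chain, kih$knob_res, kih$hole_chain))
  want <- unique(paste(ref$knob_chain, ref$knob_res, ref$hole_chain))
  expect_setequal(got, want)
  # knobs land exactly on the a/d register sites of the input
  expect_true(all((kih$knob_res - 1) %% 7 %in% c(0, 3)))
  expect_true(all(kih$orientation == "parallel"))
  expect_true(all(lengths(kih$hole_res) == 4))
  # hole residues live on the partner chain only
  expect_true(all(kih$hole_chain != kih$knob_chain))
})

test_that("knob positions match input register for n = 2, 3, 4", {
  for (n in 2:4) {
    par <- list(`2` = c(4.9, -180, 26), `3` = c(6.4, -170, 16),
                `4` = c(6.8, -213, 15))[[as.character(n)]]
    p <- helix_params(radius = par[1], pitch = par[2],
                      interface_angle = par[3],
                      sequence = strrep("IAALKQE", 4),
                      register = strrep("abcdefg", 4))
    aa <- place_sidechains(
      build_assembly(assembly_spec("basic", "coiled_coil", n, list(p)))$model)
    kih <- find_kih(aa)
    expect_gt(nrow(kih), 0)
    expect_true(all((kih$knob_res - 1) %% 7 %in% c(0, 3)))
    # interior a/d sites are detected as knobs on every chain
    interior_ad <- intersect(seq(8, 21), c(seq(1, 28, 7), seq(4, 28, 7)))
    for (ch in unique(aa$chain)) {
      found <- kih$knob_res[kih$knob_chain == ch]
      expect_true(all(interior_ad %in% found),
                  label = sprintf("n=%d chain %s interior a/d knobs", n, ch))
    }
  }
})

test_that("contacts vanish for separated chains and grow with cutoff", {
  aa <- canonical_dimer_allatom()
  apart <- aa
  sel <- apart$chain == "B"
  apart$x[sel] <- apart$x[sel] + 50
  expect_equal(nrow(find_kih(apart)), 0)
  k5 <- find_kih(aa, cutoff = 5.0)
  k7 <- find_kih(aa, cutoff = 7.0)
  expect_true(all(paste(k5$knob_chain, k5$knob_res, k5$hole_chain) %in%
                    paste(k7$knob_chain, k7$knob_res, k7$hole_chain)))
  expect_lte(nrow(k5), nrow(k7))
})

test_that("the contact list is rigid-motion invariant", {
  aa <- canonical_dimer_allatom()
  k0 <- find_kih(aa)
  k1 <- find_kih(transform_model(aa, random_rotation(5), c(-7, 13, 2)))
  cols <- c("knob_chain", "knob_res", "hole_chain", "complementarity",
            "orientation")
  expect_equal(as.data.frame(k0)[cols], as.data.frame(k1)[cols])
})

test_that("register assignment recovers the input register", {
  aa <- canonical_dimer_allatom()
  kih <- find_kih(aa)
  reg <- assign_register(kih, aa)
  # interior positions of the recovered register match the input
  for (ch in c("A", "B")) {
    got <- substr(reg$register[reg$chain == ch], 8, 21)
    expect_equal(got, substr(strrep("abcdefg", 4), 8, 21))
  }
  expect_true(all(reg$confidence > 0.8))
})

test_that("antiparallel contacts are flagged and register still recovered", {
  aa <- place_sidechains(
    build_assembly(example_specs("cc-dimer-antiparallel"))$model)
  kih <- find_kih(aa)
  expect_gt(nrow(kih), 0)
  expect_true(all(kih$orientation == "antiparallel"))
  reg <- assign_register(kih, aa)
  ok <- !is.na(reg$register)
  expect_true(any(ok))
  for (ch in reg$chain[ok]) {
    got <- substr(reg$register[reg$chain == ch], 8, 21)
    expect_equal(got, substr(strrep("abcdefg", 4), 8, 21))
  }
})

test_that("degenerate inputs give unassigned results, not errors", {
  aa <- canonical_dimer_allatom()
  apart <- aa
  apart$x[apart$chain == "B"] <- apart$x[apart$chain == "B"] + 50
  kih <- find_kih(apart)
  reg <- assign_register(kih, apart)
  expect_true(all(is.na(reg$register)))
  expect_error(find_kih(build_assembly(canonical_dimer_spec())$model),
               "place_sidechains")
})
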