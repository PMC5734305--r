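test_that("validation enforces the build-mode contracts", {
  p <- helix_params(radius = 5, pitch = -200, sequence = "GPOGPOGPO")
  # 'O' is hydroxyproline, collagen mode only
  expect_error(
    validate_spec(assembly_spec("basic", "coiled_coil", 2, list(p))),
    "O.*collagen")
  expect_silent(validate_spec(assembly_spec("advanced", "collagen", 3,
                                            list(p, p, p))))
  # collagen locked to three strands
  expect_error(
    validate_spec(assembly_spec("advanced", "collagen", 4, list(p, p, p, p))),
    "locked to an oligomeric state of 3")
  expect_error(validate_spec(assembly_spec("basic", "coiled_coil", 1,
                                           list(p))), ">= 2")
  # register/sequence length mismatch caught at construction
  expect_error(helix_params(radius = 5, pitch = -200, sequence = "IAALKQE",
                            register = "abc"),
               class = "coilr_validation_error")
})

test_that("basic mode replicates helix 1 with symmetric rotations", {
  p <- helix_params(radius = 6.8, pitch = -213, interface_angle = 26,
                    sequence = strrep("IAALKQE", 2),
                    register = strrep("abcdefg", 2))
  spec <- validate_spec(assembly_spec("basic", "coiled_coil", 4, list(p)))
  shr <- vapply(spec$helices, function(h) h$super_helical_rotation, numeric(1))
  expect_equal(shr, norm_angle(c(0, 90, 180, 270)))
  expect_true(all(vapply(spec$helices, function(h) h$radius, numeric(1)) == 6.8))
})

test_that("missing registers are auto-assigned with a warning recorded", {
  p <- helix_params(radius = 5, pitch = -200, sequence = strrep("IAALKQE", 2))
  built <- build_assembly(assembly_spec("basic", "coiled_coil", 2, list(p)))
  expect_match(built$report$warnings, "register auto-assigned", all = FALSE)
  expect_equal(validate_spec(built$report$spec)$helices[[1]]$register,
               strrep("abcdefg", 2))
})

test_that("assemblies are deterministic with one chain per helix", {
  spec <- canonical_dimer_spec()
  m1 <- build_assembly(spec)$model
  m2 <- build_assembly(spec)$model
  expect_identical(m1, m2)
  expect_equal(unique(m1$chain), c("A", "B"))
  for (name in c("cc-pentamer", "cc-heptamer-slipped")) {
    s <- example_specs(name)
    m <- build_assembly(s)$model
    expect_equal(dplyr::n_distinct(m$chain), s$oligomer_state)
  }
  expect_equal(chain_ids(28)[27:28], c("AA", "AB"))
})

test_that("advanced mode decouples per-helix parameters", {
  spec <- example_specs("cc-heterodimer-a4b4")
  m <- build_assembly(spec)$model
  expect_true("GLU" %in% m$res_name[m$chain == "A"])
  expect_true("LYS" %in% m$res_name[m$chain == "B"])
  expect_false("LYS" %in% m$res_name[m$chain == "A"])
  # length-mismatched chains are allowed in advanced mode
  ab <- build_assembly(example_specs("cc-heterodimer-a3b4"))
  expect_equal(unname(ab$report$residue_counts), c(21L, 28L))
  # slipped chain equals the unslipped chain translated axially
  sl <- example_specs("cc-heptamer-slipped")
  m_sl <- build_assembly(sl)$model
  unslipped <- sl
  unslipped$helices[[2]]$z_shift <- 0
  m_un <- build_assembly(unslipped)$model
  b_sl <- as.matrix(m_sl[m_sl$chain == "B", c("x", "y", "z")])
  b_un <- as.matrix(m_un[m_un$chain == "B", c("x", "y", "z")])
  expect_equal(b_sl, b_un + rep(c(0, 0, 1), each = nrow(b_sl)),
               tolerance = 1e-12)
})

test_that("basic to advanced promotion preserves the model exactly", {
  basic <- validate_spec(canonical_dimer_spec())
  advanced <- assembly_spec("advanced", "coiled_coil", 2, basic$helices)
  expect_identical(build_assembly(basic)$model, build_assembly(advanced)$model)
})

test_that("antiparallel dimers have opposed chain directions", {
  m <- build_assembly(example_specs("cc-dimer-antiparallel"))$model
  ca <- m[m$atom == "CA", ]
  va <- diff(ca$z[ca$chain == "A"])
  vb <- diff(ca$z[ca$chain == "B"])
  expect_lt(sum(sign(va) * sign(vb)), 0)
})

test_that("JSON specs round-trip and reject malformed documents", {
  spec <- example_specs("cc-trimer")
  json <- spec_to_json(spec)
  back <- spec_from_json(json)
  expect_identical(spec_to_json(back), json)
  expect_identical(build_assembly(back)$model, build_assembly(spec)$model)
  expect_error(spec_from_json('{"mode":"basic","oligomer_state":2}'),
               "helices")
  expect_error(spec_from_json(
    '{"mode":"basic","oligomer_state":2,"helices":[{"radius":5}]}'),
    "pitch")
  expect_error(spec_from_json(
    '{"mode":"basic","oligomer_state":2,"bogus":1,"helices":[]}'),
    "bogus")
  # lenient numerics: a numeric string is coerced
  ok <- spec_from_json(paste0(
    '{"mode":"basic","fold":"coiled_coil","oligomer_state":2,',
    '"helices":[{"radius":"5.0","pitch":-200}]}'))
  expect_equal(ok$helices[[1]]$radius, 5)
})

test_that("every fixture builds without warnings", {
  for (name in names(example_specs())) {
    built <- build_assembly(example_specs(name))
    expect_length(built$report$warnings, 0)
    expect_equal(dplyr::n_distinct(built$model$chain),
                 built$report$spec$oligomer_state)
  }
})
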