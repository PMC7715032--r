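test_that("firing-type classification follows the onset/adaptation rules", {
  expect_equal(classify_firing_type(c(0, 20, 40, 60)), "weakly adapting")
  # ISIs 20, 40, 80, 160 ms: AI = (160 - 20) / (160 + 20) = 0.78
  expect_equal(classify_firing_type(cumsum(c(0, 20, 40, 80, 160))),
               "strongly adapting")
  expect_equal(classify_firing_type(c(0, 4, 8, 40, 80)), "bursting")
  expect_error(classify_firing_type(5), "fewer than 2")
})

test_that("the shipped presets express the three CA3 firing types", {
  for (ty in c("bursting", "strongly_adapting", "weakly_adapting")) {
    st <- step_protocol(cell_preset(ty))
    expect_gte(length(st), 2)
    expect_equal(classify_firing_type(st), gsub("_", " ", ty))
  }
})

test_that("presets rest stably near their nominal potential", {
  for (ty in c("weakly_adapting", "granule")) {
    p <- cell_preset(ty)
    res <- ca3net:::run_single_cell(p, 800)
    late <- res$v[res$t > 600]
    expect_lt(max(late) - min(late), 0.1)       # settled
    expect_lt(abs(mean(late) - p$v_init), 5)    # near nominal rest
    expect_length(res$spikes, 0)
  }
})
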