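# Shared fixtures: built once per test run, in code.
fx <- local({
  input <- synthetic_input()
  schedule <- default_frame_schedule()
  grid <- table2_grid()
  list(input = input, schedule = schedule, grid = grid,
       config = fit_config(),
       # quick config for tests that do many fits
       config_fast = fit_config(multistart = 2))
})

# Noiseless grid TACs are reused by several test files; memoize them.
fx_tac <- local({
  cache <- new.env(parent = emptyenv())
  function(i) {
    key <- as.character(i)
    if (is.null(cache[[key]])) {
      cache[[key]] <- model_tac(fx$grid$configs[[i]], fx$input$plasma_parent,
                                fx$input$whole_blood, fx$schedule)
    }
    cache[[key]]
  }
})
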