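# shared fixtures, all built in code

# a complete valid raw record; override any attribute by name
make_raw_record <- function(...) {
  rec <- list(
    age = 54, sex = "Male", chest_pain = 1.0, resting_bp = 130,
    serum_cholesterol = 220, fasting_blood_sugar = "False",
    resting_ecg = "Normal", diabetes = "No", exercise_angina = "No",
    st_depression = "Flat", st_slope = 0.2, smoke = "No",
    heart_status = "Normal", heart_disease = "No", major_vessels = 1,
    max_heart_rate = 80)
  utils::modifyList(rec, list(...))
}

# tiny two-layer network for fast protocol tests
tiny_arch <- function(p = 3, alpha = 0.5) architecture(c(p, 2, 1), alpha = alpha)

# dataset with p features drawn from the default schema, small n
tiny_dataset <- function(n = 20, seed = 1) {
  generate_dataset(generator_config(n = n, seed = seed))
}

# full-parameter update message from given scalar-filled tensors
scalar_update <- function(node_id, value, model, data_size = 10L, loss = 0.5) {
  tensors <- lapply(model$tensors, function(t) {
    t[] <- value
    t
  })
  update_message(node_id, "full", tensors, seq_along(tensors),
                 data_size, loss)
}

# independent double-loop evaluation of the kernel decision function
rsvm_oracle <- function(x, supports, coefs, margin, gk) {
  s <- margin
  for (j in seq_len(nrow(supports)))
    s <- s + coefs[j] * exp(-gk * sum((x - supports[j, ])^2))
  s
}
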