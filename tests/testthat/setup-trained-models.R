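# One desk-scale translation model is trained here and shared by the
# rhythm-transfer and augmentation tests, so the expensive fit runs once.
# Conditions: ~500 paired 30-s segments (mixed AF/SR, as a surgical-ward
# recording mix would be), a small U-Net (depth 3, 8 base filters), 6
# epochs of adversarial + L1 training.

shared_train_pairs <- cohort_pairs(250, af_frac = 0.5, duration_s = 60,
                                   seed = 11, id_prefix = "G")

shared_gan <- gan_train(
  shared_train_pairs,
  train_config(epochs = 6, lambda_rec = 100, seed = 5),
  generator_spec(depth = 3, base_filters = 8, kernel = 9, input_len = 3072),
  discriminator_spec(n_layers = 3, base_filters = 8, kernel = 9))

# Held-out AF records for rhythm-transfer scoring (never seen in training).
shared_heldout_af <- make_cohort(12, 1.0, 30, seed = 333, id_prefix = "HA")

# Pools for the dataset-composition experiment: a fresh cohort translated by
# the shared model, plus real AF / SR pools and a disjoint test cohort.
shared_pools <- local({
  pool_co <- make_cohort(80, 0.5, 60, seed = 777, id_prefix = "P")
  seg_all <- function(recs, rhythm, origin = "real")
    do.call(bind_stores, lapply(recs, segment_annotated, rhythm = rhythm,
                                origin = origin))
  af_par <- seg_all(Filter(function(r) r$rhythm_label == "AF", pool_co), "AF")
  sr_par <- seg_all(Filter(function(r) r$rhythm_label == "SR", pool_co), "SR")
  gen_par <- segment_store(generate_ppg(shared_gan, af_par$ecg),
                           af_par$labels, "generated",
                           paste0(af_par$parent_id, "_gen"),
                           fs = 100, segment_seconds = 30)
  list(generated_af = slice_segments(gen_par),
       real_af = slice_segments(af_par),
       real_sr = slice_segments(sr_par))
})

shared_test_store <- local({
  test_co <- make_cohort(40, 0.5, 30, seed = 9999, id_prefix = "T")
  seg_all <- function(recs, rhythm)
    do.call(bind_stores, lapply(recs, segment_annotated, rhythm = rhythm))
  bind_stores(
    slice_segments(seg_all(Filter(function(r) r$rhythm_label == "AF", test_co), "AF")),
    slice_segments(seg_all(Filter(function(r) r$rhythm_label == "SR", test_co), "SR")))
})
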