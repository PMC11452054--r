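quantity,value
epochs_segmented,15505
measurements,357
epochs_kept,15381
epochs_kept_stroke,12747
epoch_length_samples,512
sampling_rate_hz,100
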