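# Default pipeline settings: 10x variable decimation, Kennard-Stone
# 20-sample calibration split on the reference features, SVM cost grid
# {1, 10, 30, 100}, SNV + first derivative for breed discrimination.
spectra: spectra.csv
reference: reference.csv
treatments: [SM, DV1, DV2, NORM-DV1, MSC-SM, MSC-DV1, SNV-SM, ALS-SM, SNV-DV1]
keep_every: 10
n_train: 20
feature_space: reference
C_grid: [1, 10, 30, 100]
epsilon: 0.1
svc_C: 1
discrimination_treatment: SNV-DV1
seed: 42
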