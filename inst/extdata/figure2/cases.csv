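case_id,admission_ts,discharge_ts
F2,2024-03-01T10:00,2024-03-05T11:00
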