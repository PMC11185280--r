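alert_id,case_id,alert_type,severity,interactive,trigger_rx_ids,display_start_ts,display_end_ts
AL1,F2,DDI,severe,false,R1,2024-03-01T10:00,2024-03-03T12:00
AL1,F2,DDI,severe,false,R1,2024-03-03T13:00,2024-03-05T00:00
AL2,F2,DAI,moderate,false,R2,2024-03-02T08:00,2024-03-05T11:00
AL3,F2,PE_MDD,severe,false,R3,2024-03-03T09:00,2024-03-03T15:00
AL4,F2,DP,moderate,false,R4,2024-03-05T01:00,2024-03-05T11:00
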