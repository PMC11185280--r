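rx_id,case_id,drug_code,route,schedule_kind,start_ts,end_ts
R1,F2,D1,PO,regular,2024-03-01T10:00,2024-03-05T11:00
R2,F2,D2,PO,regular,2024-03-02T08:00,2024-03-05T11:00
R3,F2,D3,PO,regular,2024-03-03T09:00,2024-03-05T11:00
R4,F2,D4,PO,regular,2024-03-04T12:00,2024-03-05T11:00
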