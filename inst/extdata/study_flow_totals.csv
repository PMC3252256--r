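flow_type,amount_ddd
discard,10.5
discharge_takeaway,18.0
loan_out,14.5
loan_in,9.0
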