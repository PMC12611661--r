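# Default adjudication codebook.  The exact regional code lists are
# configurable by design: edit the sets below and pass the file to
# read_codebook() / run_config(codebook_path=).
park_atc: [N04BA, N04BC, N04BB, N04BD, N04BX, N04AA]
park_exemption: ['038']
dementia_atc: [N06DA, N06DX01]
proxy_atc: [N05A, N06AX05, N06AX11]
dementia_icd9: ['290', '294.1', '294.2', '331.0', '331.1', '331.82']
dementia_exemption: ['011']
psych_icd9: ['295', '296']
psych_exemption: ['044', '046']
repeat_min_count: 2
repeat_window_days: 365
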