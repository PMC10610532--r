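# Two-segment acquisition for the caffeoylquinic isomer groups on the fast
# short-column gradient: alternating low-energy (RI) and high-energy (PIS)
# MS/MS events per segment.
segments:
  - segment_id: 1
    group: CQAs
    rt_window: [0.0, 3.0]
    precursor_mz: 353
    ri_event: {scan_range: [300, 365], exa: 15}
    pis_event: {scan_range: [95, 250], exa: 25}
    isolation_width: 3
    q_value: 0.25
    excitation_time_ms: 50
  - segment_id: 2
    group: diCQAs
    rt_window: [3.0, 7.5]
    precursor_mz: 515
    ri_event: {scan_range: [450, 530], exa: 10}
    pis_event: {scan_range: [140, 365], exa: 30}
    isolation_width: 3
    q_value: 0.25
    excitation_time_ms: 50
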