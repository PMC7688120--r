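line_id	linetype	ne	generations
HR1	selected	35	88
HR2	selected	35	88
HR3	selected	35	88
HR4	selected	35	88
C1	control	35	88
C2	control	35	88
C3	control	35	88
C4	control	35	88
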