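{"frame_offset":0,"regions":[{"region":"FR1","start":1,"end":75},{"region":"CDR1","start":76,"end":99},{"region":"FR2","start":100,"end":150},{"region":"CDR2","start":151,"end":174},{"region":"FR3","start":175,"end":294}]}
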