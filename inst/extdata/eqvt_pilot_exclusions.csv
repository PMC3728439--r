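site,n_participants_in,n_allsame_excluded,n_fast_tasks_excluded
china,406,38,6
singapore,407,28,4
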