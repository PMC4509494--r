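{"name":"strong_effect","k":2,"mafs":[0.4,0.4],"prevalence":0.1,"table":[0.0448671931083991,0.0448671931083991,0.0448671931083991,0.0448671931083991,0.179468772433597,0.179468772433597,0.0448671931083991,0.179468772433597,0.179468772433597]}
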