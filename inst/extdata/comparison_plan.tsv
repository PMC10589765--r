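label	baseline	treatment
style_transfer	bd_augmented	bd_st
pix2pix	bd_augmented	bd_p2p
self_labeling	bd_st_p2p	bd_st_p2p_ssl
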