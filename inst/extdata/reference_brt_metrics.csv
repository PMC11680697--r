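model,interaction_depth,shrinkage,n_trees,auc,cv_auc,deviance,cv_deviance
follow_the_flow,9,0.025,7000,0.934,0.850,0.697,0.958
swim_direction,9,0.005,8600,0.857,0.801,0.744,0.829
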