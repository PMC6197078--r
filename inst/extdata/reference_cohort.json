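[{"id":"A","rho":0.17,"t_half":14,"k_hat":220,"gamma_v":0.9},{"id":"B","rho":0.07,"t_half":28,"k_hat":150,"gamma_v":0.7},{"id":"C","rho":0.08,"t_half":4,"k_hat":125,"gamma_v":0.7},{"id":"D","rho":0.02,"t_half":22,"k_hat":300,"gamma_v":0.9},{"id":"E","rho":0.02,"t_half":30,"k_hat":140,"gamma_v":0.8},{"id":"F","rho":0.1,"t_half":30,"k_hat":120,"gamma_v":0.6},{"id":"G","rho":0.1,"t_half":30,"k_hat":120,"gamma_v":0.7}]
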