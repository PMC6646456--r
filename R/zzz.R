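.onLoad <- function(libname, pkgname) {
  register_model_loader("toynet", function(weights_ref) {
    net <- toynet_load_h5(weights_ref)
    function(x) toynet_predict(net, x)
  })
}
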